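#' Paired log-ratio / FDR expression dataset
#'
#' The central data container: a genes-by-features matrix `X_LR` of log2
#' fold changes (test over control) and a parallel matrix `X_FDR` of
#' per-cell false discovery rates from the rank-product procedure. Each
#' column ("feature") is one control-test comparison of experimental
#' conditions, described in the `features` manifest.
#'
#' @param X_LR Numeric matrix, genes x features, with unique rownames
#'   (gene IDs) and colnames (feature IDs).
#' @param X_FDR Numeric matrix of the same shape, entries in [0, 1].
#' @param features Data frame with columns `feature_id`, `experiment`,
#'   `control`, `test`, one row per column of `X_LR`. If `NULL`, a
#'   minimal manifest is synthesized from the colnames.
#' @return An `ExpressionDataset` object.
#' @export
expression_dataset <- function(X_LR, X_FDR, features = NULL) {
  stopifnot(is.matrix(X_LR), is.matrix(X_FDR))
  if (!identical(dim(X_LR), dim(X_FDR)))
    stop("X_LR and X_FDR must have identical dimensions")
  if (is.null(rownames(X_LR)) || anyDuplicated(rownames(X_LR)))
    stop("X_LR needs unique gene rownames")
  if (is.null(colnames(X_LR)) || anyDuplicated(colnames(X_LR)))
    stop("X_LR needs unique feature colnames")
  if (!identical(dimnames(X_LR), dimnames(X_FDR)))
    stop("X_LR and X_FDR must share dimnames")
  if (anyNA(X_FDR) || any(X_FDR < 0 | X_FDR > 1))
    stop("X_FDR entries must lie in [0, 1]")
  if (is.null(features)) {
    features <- data.frame(feature_id = colnames(X_LR),
                           experiment = NA_character_,
                           control = NA_character_,
                           test = NA_character_,
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(features) == ncol(X_LR),
            all(c("feature_id", "experiment", "control", "test") %in%
                  names(features)))
  if (!identical(as.character(features$feature_id), colnames(X_LR)))
    stop("features manifest must match X_LR column order")
  structure(list(X_LR = X_LR, X_FDR = X_FDR,
                 features = features,
                 gene_ids = rownames(X_LR)),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d log-ratio features\n",
              nrow(x$X_LR), ncol(x$X_LR)))
  cat(sprintf("  FDR < 0.1 in %.1f%% of cells\n",
              100 * mean(x$X_FDR < 0.1)))
  invisible(x)
}

#' Positive/negative training set for one biological process
#'
#' @param positives Character vector of positive gene IDs (C+).
#' @param negatives Character vector of negative gene IDs (C-).
#' @param process_term Ontology term ID the classes refer to.
#' @param negative_terms Optional character vector of the terms used to
#'   define the negatives.
#' @return A `TrainingSet` object.
#' @export
training_set <- function(positives, negatives,
                         process_term = NA_character_,
                         negative_terms = character()) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(positives) == 0L) stop("positive class must be nonempty")
  if (length(intersect(positives, negatives)))
    stop("positives and negatives overlap: ",
         paste(utils::head(intersect(positives, negatives), 5),
               collapse = ", "))
  structure(list(process_term = process_term,
                 positives = positives,
                 negatives = negatives,
                 negative_terms = negative_terms),
            class = "TrainingSet")
}

#' @export
print.TrainingSet <- function(x, ...) {
  cat(sprintf("TrainingSet for %s: %d positives, %d negatives\n",
              x$process_term, length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Restrict a training set to the genes of a dataset
#'
#' Genes absent from the expression matrix are dropped from both classes
#' with a warning, as they cannot take part in training.
#'
#' @param training A [training_set()].
#' @param dataset An [expression_dataset()].
#' @return The filtered `TrainingSet`.
#' @export
attach_training <- function(training, dataset) {
  keep_p <- training$positives %in% dataset$gene_ids
  keep_n <- training$negatives %in% dataset$gene_ids
  dropped <- sum(!keep_p) + sum(!keep_n)
  if (dropped > 0)
    warning(sprintf("%d training genes absent from dataset were dropped",
                    dropped))
  training_set(training$positives[keep_p], training$negatives[keep_n],
               training$process_term, training$negative_terms)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_matrix <- function(m, path) {
  df <- as.data.frame(apply(m, 2, fmt_num), stringsAsFactors = FALSE)
  df <- cbind(gene_id = rownames(m), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read an expression dataset as tab-delimited tables
#'
#' `write_dataset()` emits `<prefix>_lr.tsv`, `<prefix>_fdr.tsv` and a
#' 4-column `<prefix>_features.tsv` manifest. Values are written with 17
#' significant digits so the round trip is bit-identical.
#'
#' @param dataset An [expression_dataset()].
#' @param prefix Path prefix for the three files.
#' @return `write_dataset()` returns the prefix invisibly;
#'   `read_dataset()` returns the `ExpressionDataset`.
#' @export
write_dataset <- function(dataset, prefix) {
  write_tsv_matrix(dataset$X_LR, paste0(prefix, "_lr.tsv"))
  write_tsv_matrix(dataset$X_FDR, paste0(prefix, "_fdr.tsv"))
  utils::write.table(dataset$features, paste0(prefix, "_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  X_LR <- read_tsv_matrix(paste0(prefix, "_lr.tsv"))
  X_FDR <- read_tsv_matrix(paste0(prefix, "_fdr.tsv"))
  features <- utils::read.table(paste0(prefix, "_features.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE,
                                colClasses = "character")
  expression_dataset(X_LR, X_FDR, features)
}

#' Write / read training labels as a two-column table
#'
#' @param training A [training_set()].
#' @param path File path; columns `gene_id`, `label` (`positive`/`negative`).
#' @param process_term Term recorded when reading back.
#' @return The path (write) or a `TrainingSet` (read).
#' @export
write_labels <- function(training, path) {
  df <- data.frame(
    gene_id = c(training$positives, training$negatives),
    label = c(rep("positive", length(training$positives)),
              rep("negative", length(training$negatives))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, process_term = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  training_set(df$gene_id[df$label == "positive"],
               df$gene_id[df$label == "negative"],
               process_term)
}
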