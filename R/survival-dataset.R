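#' Construct a survival dataset with expression covariates
#'
#' Bundles an expression matrix with per-sample follow-up time, event
#' indicator, and an optional group label, validating the joint contract
#' required by the model-fitting functions.
#'
#' @param expression numeric matrix, samples in rows, genes in columns.
#' @param times positive follow-up times (relapse-free survival), one per
#'   sample, in a consistent unit (years by convention).
#' @param events 0/1 event indicator (1 = relapse or death observed).
#' @param sample_ids character sample identifiers; defaults to the matrix
#'   row names or `sample_1 ...`.
#' @param gene_names character gene identifiers; defaults to column names or
#'   `gene_1 ...`.
#' @param group optional per-sample categorical label (e.g., an externally
#'   supplied genetic-risk classification).
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `expression`, `times`, `events`, `sample_ids`, `gene_names`, `group`.
#' @export
survival_dataset <- function(expression, times, events,
                             sample_ids = NULL, gene_names = NULL,
                             group = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  if (length(times) != n)
    stop_input("length(times) [", length(times), "] != number of samples [", n, "]")
  if (length(events) != n)
    stop_input("length(events) [", length(events), "] != number of samples [", n, "]")
  if (any(!is.finite(expression)))
    stop_input("expression matrix contains non-finite values")
  if (any(!is.finite(times)) || any(times <= 0))
    stop_input("times must be finite and strictly positive")
  if (!all(events %in% c(0, 1)))
    stop_input("events must be 0/1")
  sample_ids <- as.character(sample_ids %||% rownames(expression) %||%
                               paste0("sample_", seq_len(n)))
  gene_names <- as.character(gene_names %||% colnames(expression) %||%
                               (if (ncol(expression) > 0) paste0("gene_", seq_len(ncol(expression))) else character(0)))
  if (anyDuplicated(sample_ids))
    stop_input("duplicate sample ids: ",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_names))
    stop_input("duplicate gene names: ",
               paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  if (length(gene_names) != ncol(expression))
    stop_input("gene_names length does not match expression columns")
  if (!is.null(group) && length(group) != n)
    stop_input("group must have one label per sample")
  rownames(expression) <- sample_ids
  colnames(expression) <- gene_names
  structure(list(expression = expression,
                 times = as.numeric(times),
                 events = as.integer(events),
                 sample_ids = sample_ids,
                 gene_names = gene_names,
                 group = group),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("survival_dataset:", length(x$times), "samples x",
      length(x$gene_names), "genes;",
      sum(x$events), "events (",
      round(100 * mean(x$events), 1), "% ), median follow-up ",
      signif(median(x$times), 3), "\n", sep = " ")
  invisible(x)
}

n_samples <- function(data) length(data$times)
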