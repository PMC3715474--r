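# Co-expression evaluation: build a Pearson correlation network over genes,
# spread known function labels across it with label propagation, and score
# each function term by the cross-validated area under the precision-recall
# curve (AUP). Good normalization removes confounder-driven spurious edges
# without destroying true co-functional correlation.

#' Pearson co-expression network
#'
#' Pairwise Pearson correlation of gene columns across subjects, mapped to
#' non-negative edge weights: `abs` (default, |r|), `positive`
#' (`max(r, 0)`), or `shifted` (`(r + 1)/2`). The diagonal is zeroed.
#' Constant genes have undefined correlations; their rows/columns are
#' zeroed with a warning.
#'
#' @param residual Subjects-by-genes (residual) expression matrix with at
#'   least 3 subjects.
#' @param transform Weight transform (see above).
#' @return A symmetric genes-by-genes weight matrix of class
#'   `coexpression_network`.
#' @export
pearson_network <- function(residual, transform = c("abs", "positive", "shifted")) {
  transform <- match.arg(transform)
  if (nrow(residual) < 3) stop("network construction needs >= 3 subjects", call. = FALSE)
  r <- suppressWarnings(cor(residual))
  bad <- !is.finite(r)
  if (any(bad)) {
    const <- unique(colnames(r)[which(bad, arr.ind = TRUE)[, 2]])
    warning(sprintf("%d constant gene(s) zeroed in the network: %s",
                    length(const), paste(head(const, 5), collapse = ", ")),
            call. = FALSE)
    r[bad] <- 0
  }
  w <- switch(transform,
              abs = abs(r),
              positive = pmax(r, 0),
              shifted = (r + 1) / 2)
  diag(w) <- 0
  structure(w, class = c("coexpression_network", class(w)))
}

#' Filter function terms by size after excluding unreliable evidence
#'
#' Annotation rows with excluded evidence codes (default IEA, electronically
#' inferred and not manually curated) are dropped first; then only terms
#' whose remaining gene count lies in `[min_size, max_size]` (inclusive)
#' are kept.
#'
#' @param annotations Tibble with columns `gene_id`, `term_id`, `evidence`.
#' @param min_size,max_size Inclusive bounds on term size (defaults 30 and
#'   300).
#' @param exclude_codes Evidence codes to drop (default `"IEA"`).
#' @return A named list of gene-id vectors, one per surviving term
#'   (class `function_labels`).
#' @export
filter_labels <- function(annotations, min_size = 30, max_size = 300,
                          exclude_codes = "IEA") {
  annotations <- tibble::as_tibble(annotations)
  need <- c("gene_id", "term_id", "evidence")
  if (!all(need %in% names(annotations))) {
    stop("annotations need columns gene_id, term_id, evidence", call. = FALSE)
  }
  kept <- annotations |>
    dplyr::filter(!.data$evidence %in% exclude_codes) |>
    dplyr::distinct(.data$term_id, .data$gene_id)
  sets <- split(kept$gene_id, kept$term_id)
  sets <- sets[lengths(sets) >= min_size & lengths(sets) <= max_size]
  structure(sets, class = "function_labels")
}

#' Label propagation over a co-expression network
#'
#' Solves `(I - alpha S) f = (1 - alpha) y` where
#' `S = D^{-1/2} W D^{-1/2}` is the symmetrically degree-normalized weight
#' matrix and `y` holds +1/-1 for labeled genes and 0 for unlabeled ones.
#' Isolated (degree-0) genes receive `f = (1 - alpha) y`.
#'
#' @param net A `coexpression_network`.
#' @param y Numeric label vector over the network's genes (+1 / -1 / 0).
#' @param alpha Propagation strength in (0, 1), default 0.95.
#' @param Minv Optional precomputed inverse of `I - alpha S` (see
#'   [propagation_operator()]); speeds up repeated calls with the same
#'   network.
#' @return Named numeric score vector over genes.
#' @export
label_propagation <- function(net, y, alpha = 0.95, Minv = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (length(y) != ncol(net)) stop("label vector length must match network size", call. = FALSE)
  if (is.null(Minv)) Minv <- propagation_operator(net, alpha)
  f <- as.vector(Minv %*% ((1 - alpha) * y))
  names(f) <- colnames(net)
  f
}

#' Precompute the label-propagation solve operator
#'
#' Returns `(I - alpha S)^{-1}` for reuse across many label vectors on the
#' same network (as in cross-validation, where only `y` changes).
#'
#' @inheritParams label_propagation
#' @return A genes-by-genes matrix.
#' @export
propagation_operator <- function(net, alpha = 0.95) {
  d <- rowSums(net)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  s <- net * (inv_sqrt %o% inv_sqrt)
  solve(diag(nrow(net)) - alpha * s)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) PR area: genes are ranked by decreasing
#' score and the area accumulates precision at each retrieved positive
#' times the recall increment. A single positive ranked r-th of N gives
#' `1/r`. Ties are broken by original order, deterministically.
#'
#' @param scores Numeric prediction scores.
#' @param is_positive Logical vector marking true positives.
#' @return AUP in (0, 1].
#' @export
aup <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  npos <- sum(is_positive)
  if (npos == 0) return(NA_real_)
  ord <- order(-scores)
  hits <- is_positive[ord]
  prec_at_hit <- cumsum(hits)[hits] / which(hits)
  sum(prec_at_hit) / npos
}

#' Cross-validated mean AUP of function prediction from a network
#'
#' For each function term, genes are split into stratified folds (positives
#' and negatives separately); in each fold the held-out genes' labels are
#' hidden (set to 0), labels are propagated from the training genes
#' (+1 positives, -1 negatives), and AUP is computed over the held-out
#' genes only. A term's AUP is the mean over folds; the summary is the
#' mean over terms. Terms with fewer positives than folds are skipped.
#'
#' @param net A `coexpression_network`.
#' @param labels A `function_labels` list (term -> gene ids); genes not in
#'   a term count as negatives for that term.
#' @param folds Number of CV folds (default 5).
#' @param alpha Propagation strength (default 0.95).
#' @param seed Seed for the fold assignment.
#' @return A list with `mean_aup` and `per_term` (tibble: `term_id`,
#'   `n_pos`, `aup`).
#' @export
cross_validated_aup <- function(net, labels, folds = 5, alpha = 0.95, seed = 1) {
  genes <- colnames(net)
  Minv <- propagation_operator(net, alpha)
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rows <- list()
  skipped <- 0L
  for (term in names(labels)) {
    pos <- intersect(labels[[term]], genes)
    if (length(pos) < folds) {
      skipped <- skipped + 1L
      next
    }
    neg <- setdiff(genes, pos)
    fold_of <- setNames(integer(length(genes)), genes)
    fold_of[sample(pos)] <- rep_len(seq_len(folds), length(pos))
    fold_of[sample(neg)] <- rep_len(seq_len(folds), length(neg))
    y_full <- ifelse(genes %in% pos, 1, -1)
    fold_aup <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- fold_of[genes] == f
      y <- y_full
      y[test] <- 0
      sc <- label_propagation(net, y, alpha, Minv = Minv)
      fold_aup[f] <- aup(sc[test], y_full[test] == 1)
    }
    rows[[term]] <- tibble::tibble(term_id = term, n_pos = length(pos),
                                   aup = mean(fold_aup, na.rm = TRUE))
  }
  if (skipped > 0) {
    message(sprintf("skipped %d term(s) with fewer positives than folds", skipped))
  }
  per_term <- dplyr::bind_rows(rows)
  list(mean_aup = if (nrow(per_term)) mean(per_term$aup) else NA_real_,
       per_term = per_term)
}
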