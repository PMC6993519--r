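#' Names of the six meat-quality traits used by the index
#' @export
quality_traits <- c("marbling", "wbsf", "cooking_loss", "juiciness",
                    "tenderness", "connective_tissue")

#' Composite meat-quality index from trait PCA
#'
#' Runs a correlation-matrix PCA on the standardized traits and builds for
#' each animal `index_i = sum_{j=1..n_pcs} PCS_ij * PCW_j`, where `PCS_ij`
#' is the animal's score on PC j and the weight `PCW_j` is that PC's
#' eigenvalue. Traits are standardized because they live on incommensurate
#' scales (score points, kg, %, 1-8 panels). PC signs are fixed so the
#' largest-magnitude trait loading of each component is positive.
#'
#' @param phenotypes `data.frame` holding the trait columns (see
#'   [quality_traits]) and an `animal_id` column (or rownames).
#' @param n_pcs Number of leading PCs combined into the index (default 3).
#' @param traits Trait column names (default the six standard traits).
#' @return List of class `quality_index`: `index` (named per animal),
#'   `scores` (animals x PCs), `weights` (eigenvalues of the retained PCs),
#'   `explained_variance` (fraction per PC, all PCs), `loadings`.
#' @export
compute_index <- function(phenotypes, n_pcs = 3, traits = quality_traits) {
  if (!all(traits %in% names(phenotypes)))
    stop("missing trait columns: ",
         paste(setdiff(traits, names(phenotypes)), collapse = ", "))
  if (length(traits) < n_pcs) stop("need at least n_pcs traits")
  X <- as.matrix(phenotypes[, traits, drop = FALSE])
  ids <- if ("animal_id" %in% names(phenotypes))
    as.character(phenotypes$animal_id) else rownames(phenotypes)
  if (anyNA(X)) stop("trait values must be complete for indexed animals")
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) {
    warning("all traits constant: PC scores are zero, all indices equal")
    scores <- matrix(0, nrow(X), length(traits),
                     dimnames = list(ids, paste0("PC", seq_along(traits))))
    return(structure(list(index = setNames(rep(0, nrow(X)), ids),
                          scores = scores, weights = rep(0, n_pcs),
                          explained_variance = rep(NA_real_, length(traits)),
                          loadings = NULL),
                     class = "quality_index"))
  }
  if (any(sds == 0))
    stop("degenerate PCA: constant trait column(s): ",
         paste(traits[sds == 0], collapse = ", "))
  Z <- scale(X)
  eg <- eigen(cor(X), symmetric = TRUE)
  vec <- eg$vectors
  for (j in seq_len(ncol(vec)))       # sign convention
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  scores <- Z %*% vec
  dimnames(scores) <- list(ids, paste0("PC", seq_along(traits)))
  rownames(vec) <- traits
  weights <- eg$values[seq_len(n_pcs)]
  index <- as.numeric(scores[, seq_len(n_pcs), drop = FALSE] %*% weights)
  structure(list(index = setNames(index, ids), scores = scores,
                 weights = weights,
                 explained_variance = eg$values / sum(eg$values),
                 loadings = vec),
            class = "quality_index")
}

#' @export
print.quality_index <- function(x, ...) {
  cat(sprintf("quality_index for %d animals; first %d PCs explain %s%% each\n",
              length(x$index), length(x$weights),
              paste(sprintf("%.1f", 100 * x$explained_variance[seq_along(x$weights)]),
                    collapse = " / ")))
  invisible(x)
}

#' Select animals with extreme index values
#'
#' Returns the `n_select / 2` highest-index and `n_select / 2` lowest-index
#' animals; `n_select` must be even so the two tails balance. Ties are
#' broken deterministically by animal id.
#'
#' @param index Named numeric vector of index values (or a `quality_index`).
#' @param n_select Number of animals to keep (default 80).
#' @return Character vector of selected animal ids (sorted), with
#'   attributes `high` and `low` naming the two tails.
#' @export
select_extremes <- function(index, n_select = 80) {
  if (inherits(index, "quality_index")) index <- index$index
  if (is.null(names(index))) stop("index must be named by animal id")
  if (n_select %% 2 != 0) stop("n_select must be even (balanced tails)")
  if (n_select > length(index)) stop("n_select exceeds number of animals")
  if (length(unique(index)) == 1 && n_select < length(index))
    warning("all index values equal: selection falls back to animal-id order")
  k <- n_select / 2
  hi <- names(index)[order(-index, names(index))][seq_len(k)]
  rest <- index[setdiff(names(index), hi)]
  lo <- names(rest)[order(rest, names(rest))][seq_len(k)]
  structure(sort(c(hi, lo)), high = sort(hi), low = sort(lo))
}
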