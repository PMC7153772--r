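# ADASYN adaptive synthetic oversampling of the minority (preterm) class.
#
# Density-ratio weighted interpolation: minority points surrounded by more
# majority neighbours receive more synthetic offspring, so new samples
# concentrate near the class boundary. Neighbourhoods for the density ratio
# are taken over the full dataset on z-scored features (the raw features
# span many orders of magnitude); interpolation partners are the k nearest
# minority neighbours. Synthesis is linear interpolation in the original
# feature space: s = x_i + lambda * (x_z - x_i), lambda ~ U(0, 1).

#' ADASYN configuration
#'
#' @param k_neighbors Neighbourhood size (default 5, the original
#'   algorithm's setting).
#' @param beta Balance level in \[0, 1\]; 1 fully balances the classes.
#' @param seed Integer seed controlling allocation and interpolation draws.
#' @return A list of class `adasyn_config`.
#' @export
adasyn_config <- function(k_neighbors = 5L, beta = 1, seed = 1L) {
  stopifnot(k_neighbors >= 1L, beta >= 0, beta <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors), beta = beta,
                 seed = as.integer(seed)),
            class = "adasyn_config")
}

knn_indices <- function(D, i, k, candidates) {
  cand <- setdiff(candidates, i)
  cand[order(D[i, cand])][seq_len(min(k, length(cand)))]
}

#' ADASYN oversampling of the minority class
#'
#' Generates `G = round((n_majority - n_minority) * beta)` synthetic
#' minority rows, allocated across minority points proportionally to the
#' fraction of majority points among each point's `k` nearest neighbours
#' (largest-remainder rounding, so the allocation sums to `G` exactly).
#' If every minority point has a purely minority neighbourhood the
#' allocation falls back to uniform, with a warning.
#'
#' @param data A [labeled_dataset()] (single timing contrast) whose
#'   `outcome` has both classes; the minority class is detected
#'   automatically (PRETERM in the intended use).
#' @param cfg An [adasyn_config()].
#' @return A `balanced_dataset`: list with `features` (original +
#'   synthetic rows), `outcome`, `group`, `is_synthetic`, and `provenance`
#'   (data frame: `parent`, `neighbor`, `lambda` per synthetic row).
#' @export
adasyn_oversample <- function(data, cfg = adasyn_config()) {
  X <- data$features
  y <- data$outcome
  if (any(!is.finite(X))) stop("adasyn: non-finite features")
  tab <- table(y)
  if (length(tab) < 2L || any(tab == 0L)) stop("adasyn: both classes required")
  minority <- names(tab)[which.min(tab)]
  imin <- which(y == minority)
  imaj <- which(y != minority)
  if (length(imin) < 2L) stop("adasyn: minority class needs >= 2 points")
  G <- round((length(imaj) - length(imin)) * cfg$beta)
  prov <- data.frame(parent = integer(0), neighbor = integer(0),
                     lambda = numeric(0))
  if (G > 0) {
    mu <- colMeans(X)
    sdev <- apply(X, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    Z <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
    D <- as.matrix(stats::dist(Z))
    k <- cfg$k_neighbors
    r <- vapply(imin, function(i) {
      nb <- knn_indices(D, i, k, seq_len(nrow(X)))
      mean(nb %in% imaj)
    }, numeric(1))
    if (sum(r) == 0) {
      warning("adasyn: no majority neighbours anywhere; uniform allocation")
      r <- rep(1, length(imin))
    }
    rhat <- r / sum(r)
    # largest-remainder rounding of g_i = G * rhat_i
    gre <- G * rhat
    g <- floor(gre)
    rem <- G - sum(g)
    if (rem > 0) {
      extra <- order(gre - g, decreasing = TRUE)[seq_len(rem)]
      g[extra] <- g[extra] + 1L
    }
    set.seed(cfg$seed)
    rows <- list()
    for (ii in seq_along(imin)) {
      if (g[ii] == 0L) next
      i <- imin[ii]
      nbmin <- knn_indices(D, i, k, imin)
      for (s in seq_len(g[ii])) {
        z <- nbmin[sample.int(length(nbmin), 1L)]
        lam <- stats::runif(1)
        rows[[length(rows) + 1L]] <- c(parent = i, neighbor = z, lambda = lam)
      }
    }
    prov <- as.data.frame(do.call(rbind, rows))
    prov$parent <- as.integer(prov$parent)
    prov$neighbor <- as.integer(prov$neighbor)
  }
  Xs <- if (nrow(prov)) {
    X[prov$parent, , drop = FALSE] +
      prov$lambda * (X[prov$neighbor, , drop = FALSE] -
                       X[prov$parent, , drop = FALSE])
  } else {
    X[0, , drop = FALSE]
  }
  rownames(Xs) <- if (nrow(prov)) paste0("syn", seq_len(nrow(prov))) else NULL
  all_feat <- rbind(X, Xs)
  out_outcome <- factor(c(as.character(y),
                          rep(minority, nrow(Xs))), levels = levels(y))
  grp <- c(data$group, rep(data$group[imin[1]], nrow(Xs)))
  structure(list(features = all_feat, outcome = out_outcome, group = grp,
                 is_synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xs))),
                 provenance = prov, minority = minority, G = G),
            class = "balanced_dataset")
}
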