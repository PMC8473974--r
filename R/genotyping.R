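# Two-channel genotype calling for an allotetraploid: theta/R transform,
# per-marker cluster-model fitting, 3-genotype and 5-dosage call maps.

#' Polar transform of two-channel intensities
#'
#' `theta = (2/pi) * atan(Y/X)` and `R = X + Y`, the Infinium convention:
#' theta 0 is pure A (REF) signal, 1 pure B (ALT). Records with both
#' channels 0 get `theta = NA` (no-signal sentinel).
#'
#' @param x,y non-negative channel intensities (vectors).
#' @return data frame with columns `theta`, `r`.
#' @export
theta_r <- function(x, y) {
  if (any(x < 0) || any(y < 0)) stop("theta_r: negative intensities")
  theta <- (2 / pi) * atan2(y, x)
  theta[x == 0 & y == 0] <- NA_real_
  data.frame(theta = theta, r = x + y)
}

#' Noise-free theta of an allele dosage
#'
#' Under channel signal linear in dose with equal gains, dosage `g` of
#' ploidy `p` lands at `theta = (2/pi) * atan(g / (p - g))`: 0, 1/2, 1 for
#' the diploid grid and 0, 0.205, 0.5, 0.795, 1 for the 5-dosage grid.
#'
#' @param g B-allele dose (0..p).
#' @param ploidy total allele dose (2 or 4).
#' @return theta values in \[0, 1\].
#' @export
dosage_theta <- function(g, ploidy = 2L) {
  (2 / pi) * atan2(g, ploidy - g)
}

#' Calling-engine parameters
#'
#' @param max_k maximum number of theta clusters (default 5).
#' @param min_sd floor on fitted cluster theta standard deviations.
#' @param max_sd coherence ceiling: when every fitted cluster is more
#'   diffuse than this, the marker has no credible signal clusters at all
#'   and is classed `no_signal` (background-ratio noise spreads theta far
#'   wider than any true genotype cluster).
#' @param cluster_sep_min markers with separation below this are classed
#'   unclassifiable ("poor genotyping ability").
#' @param gentrain_min markers with a quality surrogate below this are
#'   classed unclassifiable (mirrors a GenTrain-score cut of 0.5).
#' @param nc_z no-call beyond this many cluster standard deviations.
#' @param background_frac a marker is no-signal when its median R is below
#'   this fraction of the panel-wide median marker R.
#' @return a `calling_params` list.
#' @export
calling_params <- function(max_k = 5L, min_sd = 0.01, max_sd = 0.1,
                           cluster_sep_min = 0.15, gentrain_min = 0.5,
                           nc_z = 3, background_frac = 0.1) {
  p <- list(max_k = as.integer(max_k), min_sd = min_sd, max_sd = max_sd,
            cluster_sep_min = cluster_sep_min, gentrain_min = gentrain_min,
            nc_z = nc_z, background_frac = background_frac)
  stopifnot(p$max_k >= 1, p$max_k <= 5, p$min_sd > 0, p$max_sd > p$min_sd,
            p$nc_z > 0, p$background_frac >= 0, p$background_frac < 1)
  class(p) <- "calling_params"
  p
}

# Deterministic 1-D clustering: split sorted theta at the k-1 largest gaps
# (equivalent to single-linkage at k clusters in one dimension). Returns
# cluster assignments in theta order, or NULL if k exceeds the number of
# distinct values (a zero-width gap would split identical values).
gap_segments <- function(theta, k) {
  o <- order(theta)
  th <- theta[o]
  n <- length(th)
  if (k == 1L) {
    z <- integer(n) + 1L
  } else {
    gaps <- diff(th)
    if (sum(gaps > 0) < k - 1L) return(NULL)
    cut_at <- sort(order(-gaps, seq_along(gaps))[seq_len(k - 1L)])
    z <- findInterval(seq_len(n), cut_at + 1L) + 1L
  }
  out <- integer(n)
  out[o] <- z
  out
}

# Mean silhouette of a 1-D clustering, computed directly.
silhouette_1d <- function(theta, z) {
  k <- max(z)
  if (k < 2L) return(1)
  n <- length(theta)
  d <- abs(outer(theta, theta, "-"))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- z == z[i]
    n_own <- sum(own) - 1L
    a <- if (n_own > 0) sum(d[i, own]) / n_own else 0
    b <- min(vapply(setdiff(seq_len(k), z[i]),
                    function(g) mean(d[i, z == g]), 0))
    s[i] <- if (n_own > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster separation score
#'
#' Minimum over adjacent cluster pairs of the gap between their theta
#' `+/- 2 sd` envelopes, relative to the full theta range (1.0), floored at
#' 0. Defined as 1.0 for models with fewer than two clusters.
#'
#' @param model a `cluster_model` (or any list with `means` and `sds`).
#' @return score in \[0, 1\].
#' @export
cluster_separation <- function(model) {
  k <- length(model$means)
  if (k < 2L) return(1)
  gaps <- (model$means[-1L] - 2 * model$sds[-1L]) -
    (model$means[-k] + 2 * model$sds[-k])
  max(0, min(gaps))
}

#' Fit a per-marker theta cluster model
#'
#' Samples with R above the background threshold are clustered on theta by
#' deterministic largest-gap segmentation for each `k = 1..max_k`; each
#' segmentation is scored as a 1-D Gaussian mixture (cluster standard
#' deviations floored at `min_sd`) and `k` is chosen by BIC. The fitted
#' model carries per-cluster theta mean/sd and R mean, a cluster-to-call
#' map on the arctan dosage grid (diploid for `k <= 3`, 5-dosage for
#' `k >= 4`; A-rich clusters get low theta), a silhouette-based quality
#' surrogate, the separation score, and the marker class from
#' [classify_marker()]. Everything is deterministic given the data.
#'
#' @param theta,r polar intensities per sample (from [theta_r()]).
#' @param params a [calling_params()].
#' @param r_background R at or below this value is treated as background
#'   (default 0: no exclusion). Markers with every sample at background are
#'   classed `no_signal`.
#' @param marker_id optional id stored in the model.
#' @return a `cluster_model` object.
#' @export
fit_cluster_model <- function(theta, r, params = calling_params(),
                              r_background = 0, marker_id = NULL) {
  stopifnot(length(theta) == length(r))
  if (length(theta) < 10L)
    stop("fit_cluster_model: at least 10 samples required")
  keep <- !is.na(theta) & r > r_background
  base <- structure(list(marker_id = marker_id, k = 0L, means = numeric(0),
                         sds = numeric(0), props = numeric(0),
                         r_means = numeric(0), calls = character(0),
                         class = "no_signal", gentrain = 0,
                         cluster_sep = 0, r_background = r_background,
                         n = sum(keep), params = params),
                    class = "cluster_model")
  if (stats::median(r) <= r_background || sum(keep) < 2L) return(base)
  th <- theta[keep]; rr <- r[keep]
  n <- length(th)
  n_unique <- length(unique(th))
  best <- NULL; best_bic <- Inf
  if (n_unique <= params$max_k) {
    # discrete (noise-free) data: every distinct theta is its own cluster;
    # BIC would otherwise merge rare-dosage singletons
    k <- n_unique
    z <- gap_segments(th, k)
    best <- list(k = k, z = z,
                 mu = vapply(seq_len(k), function(g) mean(th[z == g]), 0),
                 sd = rep(params$min_sd, k), pr = tabulate(z, k) / n)
  } else for (k in seq_len(min(params$max_k, n_unique))) {
    z <- gap_segments(th, k)
    if (is.null(z)) next
    mu <- vapply(seq_len(k), function(g) mean(th[z == g]), 0)
    sd_ <- vapply(seq_len(k), function(g) {
      v <- stats::sd(th[z == g]); if (is.na(v)) 0 else v
    }, 0)
    sd_ <- pmax(sd_, params$min_sd)
    pr <- tabulate(z, k) / n
    dens <- sapply(seq_len(k), function(g)
      pr[g] * stats::dnorm(th, mu[g], sd_[g]))
    ll <- sum(log(pmax(rowSums(cbind(dens)), 1e-300)))
    bic <- -2 * ll + (3 * k - 1) * log(n)
    if (bic < best_bic) {
      best_bic <- bic
      best <- list(k = k, z = z, mu = mu, sd = sd_, pr = pr)
    }
  }
  if (is.null(best)) return(base)
  ord <- order(best$mu)
  rank_map <- match(seq_len(best$k), ord)
  model <- base
  model$k <- best$k
  model$means <- best$mu[ord]
  model$sds <- best$sd[ord]
  model$props <- best$pr[ord]
  model$r_means <- vapply(ord, function(g) mean(rr[best$z == g]), 0)
  model$gentrain <- (silhouette_1d(th, rank_map[best$z]) + 1) / 2
  model$cluster_sep <- cluster_separation(model)
  # call map: nearest point on the arctan dosage grid, A-rich -> low theta
  ploidy <- if (model$k >= 4L) 4L else 2L
  grid <- dosage_theta(0:ploidy, ploidy)
  codes <- if (ploidy == 2L) DIPLOID_CODES else TETRA_CODES
  dose <- vapply(model$means, function(m) which.min(abs(grid - m)) - 1L, 0L)
  model$calls <- codes[dose + 1L]
  classify_marker(model, params)
}

#' Classify a fitted marker
#'
#' `no_signal` if the background rule fired; `monomorphic` for one cluster;
#' `polymorphic_3` for 2-3 clusters mapping to distinct AA/AB/BB calls;
#' `intergenomic_5` for 4-5 clusters (homoeolog blending);
#' `unclassifiable` when the separation score or quality surrogate is below
#' threshold or two clusters collide on the same call code (the
#' "poor genotyping ability" bucket: heterozygotes and homozygotes cannot
#' be told apart).
#'
#' @param model a `cluster_model`.
#' @param params a [calling_params()].
#' @return the model with its `class` field set.
#' @export
classify_marker <- function(model, params = calling_params()) {
  # signal evidence: at least one substantial cluster (>= 3 samples and
  # >= 5% of the panel) tighter than max_sd; background-ratio noise has
  # only diffuse or accidental tiny clusters
  coherent <- if (model$k > 0L) {
    sizes <- model$props * model$n
    any(sizes >= max(3, 0.05 * model$n) & model$sds <= params$max_sd)
  } else FALSE
  model$class <-
    if (model$k == 0L) "no_signal"
    else if (!coherent) "no_signal"
    else if (model$k == 1L) "monomorphic"
    else if (anyDuplicated(model$calls) ||
             model$cluster_sep < params$cluster_sep_min ||
             model$gentrain < params$gentrain_min) "unclassifiable"
    else if (model$k <= 3L) "polymorphic_3"
    else "intergenomic_5"
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Cluster model", if (!is.null(x$marker_id)) paste0("[", x$marker_id, "]"),
      ": k =", x$k, ", class =", x$class, "\n")
  if (x$k > 0)
    cat("  theta:", paste(sprintf("%s@%.3f", x$calls, x$means),
                          collapse = "  "),
        sprintf("| sep %.3f, quality %.3f\n", x$cluster_sep, x$gentrain))
  invisible(x)
}

#' Call samples against a fitted cluster model
#'
#' Each sample is assigned the nearest cluster by theta z-distance
#' (`|theta - mean| / sd`); no-call (`NC`) when the minimum z-distance
#' exceeds `nc_z` or R is at or below the marker's background threshold.
#'
#' @param object a `cluster_model`.
#' @param newdata data frame with columns `theta` and `r`.
#' @param ... unused.
#' @return character vector of call codes.
#' @export
predict.cluster_model <- function(object, newdata, ...) {
  stopifnot(all(c("theta", "r") %in% names(newdata)))
  n <- nrow(newdata)
  if (object$k == 0L || object$class %in% c("no_signal", "unclassifiable"))
    return(rep("NC", n))
  out <- rep("NC", n)
  ok <- !is.na(newdata$theta) & newdata$r > object$r_background
  if (any(ok)) {
    z <- abs(outer(newdata$theta[ok], object$means, "-")) /
      rep(object$sds, each = sum(ok))
    z <- matrix(z, ncol = object$k)
    jmin <- max.col(-z, ties.method = "first")
    zmin <- z[cbind(seq_len(nrow(z)), jmin)]
    calls <- object$calls[jmin]
    calls[zmin > object$params$nc_z] <- "NC"
    out[ok] <- calls
  }
  out
}

#' Draw synthetic theta/R observations from a fitted model
#'
#' @param object a `cluster_model`.
#' @param nsim observations to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with `theta`, `r`, and the generating `cluster`.
#' @export
simulate.cluster_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$k == 0L) stop("simulate.cluster_model: no-signal model")
  draw <- function() {
    g <- sample.int(object$k, nsim, replace = TRUE, prob = object$props)
    data.frame(theta = pmin(1, pmax(0, stats::rnorm(nsim, object$means[g],
                                                    object$sds[g]))),
               r = object$r_means[g], cluster = g)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Plot a fitted cluster model
#'
#' Draws the fitted Gaussian mixture density over theta with cluster means
#' marked and labelled by their call codes.
#'
#' @param x a `cluster_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cluster_model <- function(x, ...) {
  if (x$k == 0L) {
    graphics::plot(0, 0, type = "n", xlab = "theta", ylab = "density",
                   main = "no signal", xlim = c(0, 1))
    return(invisible(x))
  }
  th <- seq(0, 1, length.out = 512)
  dens <- rowSums(sapply(seq_len(x$k), function(g)
    x$props[g] * stats::dnorm(th, x$means[g], x$sds[g])))
  graphics::plot(th, dens, type = "l", xlab = "theta",
                 ylab = "mixture density",
                 main = paste0(x$marker_id %||% "marker", " (", x$class, ")"),
                 ...)
  graphics::abline(v = x$means, lty = 3)
  graphics::text(x$means, max(dens) * 0.95, x$calls, cex = 0.8)
  invisible(x)
}
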