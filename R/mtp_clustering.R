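# Stage 2: meal-timing patterns by k-means on standardised usual exposures.
# The standardisation parameters and centroids fitted here are frozen and
# reused for every multiple-imputation draw, so patterns never move (or
# switch labels) across imputations.

#' Standardise usual exposures to z-scores
#'
#' Column-wise (x - mean) / SD over the five exposures, storing the
#' parameters so the identical scaling can be reapplied to imputation draws.
#'
#' @param usual usual-exposure table (needs the [exposure_names()] columns).
#' @param params optional stored parameters (list with \code{mean},
#'   \code{sd}) to reapply instead of re-estimating.
#' @return list with \code{z} (matrix), \code{mean} and \code{sd}.
#' @export
standardize_exposures <- function(usual, params = NULL) {
  x <- as.matrix(as.data.frame(usual)[, exposure_names()])
  if (is.null(params)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, sd)
    if (any(sdv <= 0 | !is.finite(sdv))) {
      stop("constant exposure column: ",
           paste(exposure_names()[sdv <= 0], collapse = ", "))
    }
  } else {
    mu <- params$mean; sdv <- params$sd
  }
  z <- sweep(sweep(x, 2, mu, `-`), 2, sdv, `/`)
  list(z = z, mean = mu, sd = sdv)
}

kmeanspp_init <- function(z, k) {
  n <- nrow(z)
  centers <- matrix(NA_real_, k, ncol(z))
  centers[1, ] <- z[sample.int(n, 1), ]
  d2 <- rowSums(sweep(z, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- d2 / sum(d2)
    centers[j + 1, ] <- z[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(z, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Fit meal-timing patterns by k-means
#'
#' Lloyd's algorithm with k-means++ seeding, best of \code{n_starts} random
#' initialisations by within-cluster sum of squares; deterministic given
#' \code{seed}. For \code{k = 3} centroids are named by their signature (see
#' [name_patterns()]), otherwise generically.
#'
#' @param usual usual-exposure table (regression-calibration provenance).
#' @param k number of patterns (default 3).
#' @param n_starts random restarts (default 25).
#' @param seed integer seed.
#' @return An object of class \code{mtp_model}: standardisation parameters,
#'   centroids (standardised space), centroid names, inertia, \code{k},
#'   \code{n_starts}, \code{seed} and the training assignment.
#' @export
fit_mtp <- function(usual, k = 3, n_starts = 25, seed = 1L) {
  std <- standardize_exposures(usual)
  z <- std$z
  if (nrow(z) < k) stop("k exceeds the number of rows")
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      km <- tryCatch(
        stats::kmeans(z, centers = kmeanspp_init(z, k), iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed for every start")
  centroids <- unname(best$centers)
  colnames(centroids) <- exposure_names()
  model <- structure(list(
    mean = std$mean, sd = std$sd, k = k,
    centroids = centroids,
    names = rep(NA_character_, k),
    inertia = best$tot.withinss,
    n_starts = n_starts, seed = as.integer(seed)
  ), class = "mtp_model")
  model$names <- name_patterns(model)
  model$training_assignment <- model$names[best$cluster]
  model
}

#' Name pattern centroids by their exposure signature
#'
#' For \code{k = 3}: the centroid with the maximal morning-energy z-score is
#' "early-often"; of the remaining two, the one with the smaller
#' eating-window z-score is "late-infrequent-short" and the other
#' "late-long". Exact ties are broken by the evening-energy z-score (lower
#' evening energy wins "early-often"; longer window wins "late-long"). For
#' any other k the names are generic \code{pattern_1..k}.
#'
#' @param model an \code{mtp_model} (or any list with a \code{centroids}
#'   matrix).
#' @return character vector of names, one per centroid row.
#' @export
name_patterns <- function(model) {
  cen <- model$centroids
  k <- nrow(cen)
  if (k != 3) return(paste0("pattern_", seq_len(k)))
  nm <- rep(NA_character_, 3)
  morning <- cen[, "morning_pct"]
  early <- order(-morning, cen[, "evening_pct"])[1]
  nm[early] <- "early-often"
  rest <- setdiff(1:3, early)
  win <- cen[rest, "window_h"]
  short <- rest[order(win, -cen[rest, "evening_pct"])[1]]
  nm[short] <- "late-infrequent-short"
  nm[setdiff(rest, short)] <- "late-long"
  nm
}

#' Classify exposure vectors into meal-timing patterns
#'
#' Standardises with the model's stored parameters and returns the name of
#' the nearest centroid in Euclidean distance. Deterministic; exact
#' equidistance is resolved toward the lowest centroid index.
#'
#' @param model an \code{mtp_model}.
#' @param usual usual-exposure table or a single named 5-vector on natural
#'   units.
#' @return character vector of pattern names.
#' @export
assign_mtp <- function(model, usual) {
  if (is.numeric(usual) && is.null(dim(usual))) {
    usual <- as.data.frame(as.list(usual))
  }
  miss <- setdiff(exposure_names(), names(as.data.frame(usual)))
  if (length(miss)) stop("missing exposure components: ",
                         paste(miss, collapse = ", "))
  z <- standardize_exposures(usual, params = model)$z
  d2 <- sapply(seq_len(model$k), function(j)
    rowSums(sweep(z, 2, model$centroids[j, ])^2))
  d2 <- matrix(d2, nrow = nrow(z))
  model$names[max.col(-d2, ties.method = "first")]
}

#' Persist / restore an MTP model as JSON
#'
#' Plain-text artifact with standardisation parameters, centroids, names,
#' inertia and seed, for exact reuse across runs.
#'
#' @param model an \code{mtp_model}.
#' @param path file path.
#' @return \code{write_mtp_model} returns \code{path} invisibly;
#'   \code{read_mtp_model} returns the restored \code{mtp_model}.
#' @export
write_mtp_model <- function(model, path) {
  obj <- list(mean = as.list(model$mean), sd = as.list(model$sd),
              k = model$k, centroids = model$centroids,
              names = model$names, inertia = model$inertia,
              n_starts = model$n_starts, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mtp_model
#' @export
read_mtp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cen <- matrix(as.numeric(obj$centroids), nrow = obj$k)
  colnames(cen) <- exposure_names()
  structure(list(
    mean = setNames(as.numeric(obj$mean[exposure_names()]), exposure_names()),
    sd = setNames(as.numeric(obj$sd[exposure_names()]), exposure_names()),
    k = obj$k, centroids = cen, names = obj$names,
    inertia = obj$inertia, n_starts = obj$n_starts, seed = obj$seed
  ), class = "mtp_model")
}

#' @export
print.mtp_model <- function(x, ...) {
  cat("Meal-timing pattern model (k =", x$k, ")\n")
  cen <- round(x$centroids, 2)
  rownames(cen) <- x$names
  print(cen)
  cat("inertia:", signif(x$inertia, 5), "\n")
  invisible(x)
}

#' Cluster-number diagnostics
#'
#' Average silhouette width and total within-cluster sum of squares for a
#' range of k, to support the (fixed, k = 3) default choice.
#'
#' @param usual usual-exposure table.
#' @param k_range candidate cluster counts.
#' @param n_starts,seed passed to [fit_mtp()].
#' @return data.frame with \code{k}, \code{inertia},
#'   \code{avg_silhouette}.
#' @export
mtp_diagnostics <- function(usual, k_range = 2:6, n_starts = 10, seed = 1L) {
  std <- standardize_exposures(usual)
  z <- std$z
  dmat <- as.matrix(stats::dist(z))
  out <- lapply(k_range, function(k) {
    m <- fit_mtp(usual, k = k, n_starts = n_starts, seed = seed)
    lab <- assign_mtp(m, usual)
    sil <- vapply(seq_len(nrow(z)), function(i) {
      own <- lab == lab[i]; own[i] <- FALSE
      a <- if (any(own)) mean(dmat[i, own]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]), function(l)
        mean(dmat[i, lab == l]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    data.frame(k = k, inertia = m$inertia, avg_silhouette = mean(sil))
  })
  do.call(rbind, out)
}
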