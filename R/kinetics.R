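# Forster hopping rates with detailed balance, and assembly of the full
# first-order rate matrix (transfer + intrinsic decay) of a pigment network.

#' Forster energy-transfer rate from coupling and spectral overlap
#'
#' k = 1.18 V^2 J, with V in cm^-1, J in cm and k in ps^-1. The numerical
#' prefactor absorbs the fundamental constants of Forster theory when the
#' quantities are expressed in exactly these units.
#'
#' @param V Electronic coupling, cm^-1 (sign irrelevant: the rate is in V^2).
#' @param J Spectral overlap of normalized donor emission and acceptor
#'   absorption, cm (>= 0).
#' @return Transfer rate, ps^-1.
#' @export
#' @examples
#' forster_rate(1, 1)        # 1.18 ps^-1
#' forster_rate(54, 1e-4)    # rate at a typical carotenoid-bilin coupling
forster_rate <- function(V, J) {
  if (any(J < 0)) stop("spectral overlap J must be non-negative")
  1.18 * V^2 * J
}

#' Uphill rate from detailed balance
#'
#' Given the downhill rate across an energy gap `delta_e`, the uphill rate is
#' scaled by the Boltzmann factor: k_up = k_down * exp(-delta_e / (kB T)),
#' with kB = 0.6950348 cm^-1/K.
#'
#' @param k_downhill Downhill rate, ps^-1.
#' @param delta_e Site-energy gap, cm^-1 (>= 0).
#' @param temperature Kelvin (> 0).
#' @return Uphill rate, ps^-1.
#' @export
detailed_balance_pair <- function(k_downhill, delta_e, temperature = 300) {
  if (any(delta_e < 0)) stop("delta_e must be >= 0 (pass the downhill gap)")
  if (temperature <= 0) stop("temperature must be positive")
  k_downhill * exp(-delta_e / (.const$kB_cm1 * temperature))
}

#' Construct a rate matrix object
#'
#' @param transfer n x n matrix of hop rates, ps^-1; entry `[i, j]` is the
#'   rate i -> j; zero diagonal.
#' @param decay Length-n vector of intrinsic decay rates, ps^-1.
#' @param labels Pigment ids.
#' @param temperature Kelvin (recorded for provenance).
#' @return Object of class `rate_matrix`.
#' @export
rate_matrix <- function(transfer, decay, labels = NULL, temperature = 300) {
  transfer <- as.matrix(transfer)
  n <- nrow(transfer)
  if (ncol(transfer) != n || length(decay) != n)
    stop("inconsistent dimensions: transfer is ", n, "x", ncol(transfer),
         ", decay has length ", length(decay))
  if (any(transfer < 0) || any(decay < 0))
    stop("rates must be non-negative")
  if (any(diag(transfer) != 0)) stop("transfer diagonal must be zero")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  dimnames(transfer) <- list(labels, labels)
  structure(list(transfer = transfer, decay = stats::setNames(decay, labels),
                 labels = labels, temperature = temperature),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate_matrix> ", length(x$labels), " pigments, ",
      sum(x$transfer > 0), " non-zero hop rates, T = ", x$temperature,
      " K\n", sep = "")
  invisible(x)
}

# Overlap-with-memoization used by build_rate_matrix. J for fixed component
# templates depends only on the donor-acceptor 0-0 gap (shift invariance of
# the overlap), so results are cached on (donor template, acceptor template,
# gap rounded to 0.01 cm^-1).
.pair_overlap <- function(lib, donor_ls, acc_ls, e_donor, e_acc, cache) {
  key <- sprintf("%s|%s|%.2f", donor_ls, acc_ls, e_donor - e_acc)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  em <- mirror_emission(realize_lineshape(lib[[donor_ls]], e_donor,
                                          "ABSORPTION"))
  ab <- realize_lineshape(lib[[acc_ls]], e_acc, "ABSORPTION")
  j <- spectral_overlap(em, ab)
  cache[[key]] <- j
  j
}

# Directional rates for one coupled pair (indices i, j in the pigment table).
# Downhill = from the higher-energy site; for equal energies the lower index
# is taken as donor (the tie only matters for which overlap is evaluated
# directly; the reverse rate is then identical by detailed balance).
.pair_rates <- function(pg, i, j, V, lib, temperature, cache) {
  ei <- pg$E_cm1[i]; ej <- pg$E_cm1[j]
  if (ei > ej || (ei == ej && i < j)) { d <- i; a <- j } else { d <- j; a <- i }
  jint <- .pair_overlap(lib, pg$lineshape[d], pg$lineshape[a],
                        pg$E_cm1[d], pg$E_cm1[a], cache)
  k_down <- forster_rate(V, jint)
  k_up <- detailed_balance_pair(k_down, pg$E_cm1[d] - pg$E_cm1[a], temperature)
  out <- numeric(2)  # (rate i->j, rate j->i)
  if (d == i) { out[1] <- k_down; out[2] <- k_up }
  else        { out[1] <- k_up;   out[2] <- k_down }
  out
}

#' Build the full rate matrix of a pigment network
#'
#' For every coupled pair, the energetically downhill direction gets the
#' Forster rate k = 1.18 V^2 J computed from the donor's mirror-image
#' emission and the acceptor's absorption lineshape (both realized at the
#' pigments' 0-0 site energies); the uphill direction gets the
#' detailed-balance-scaled rate. The decay vector is copied from the pigment
#' table. Uncoupled pairs get zero rates both ways.
#'
#' @param network A `pigment_network` with fully assigned site properties.
#' @param lineshape_library Named list of component tables; see
#'   [default_lineshape_library()].
#' @param temperature Kelvin.
#' @param base Optional `rate_matrix` from a previous build of the same
#'   topology; entries touching pigments in `changed` are recomputed and all
#'   others reused. Used by [run_ensemble()], where only the carotenoid
#'   parameters change between runs.
#' @param changed Integer indices of pigments whose couplings, energies or
#'   decay changed since `base` was built.
#' @return A [rate_matrix()].
#' @export
build_rate_matrix <- function(network,
                              lineshape_library = default_lineshape_library(),
                              temperature = 300,
                              base = NULL, changed = NULL) {
  stopifnot(inherits(network, "pigment_network"))
  pg <- network$pigments
  validate_pigments(pg, require_properties = TRUE)
  miss <- setdiff(unique(pg$lineshape), names(lineshape_library))
  if (length(miss) > 0)
    stop("lineshape library has no entry for: ", paste(miss, collapse = ", "))
  n <- nrow(pg)
  V <- network$couplings
  cache <- new.env(parent = emptyenv())

  if (is.null(base)) {
    K <- matrix(0, n, n)
    pairs <- which(upper.tri(V) & V != 0, arr.ind = TRUE)
  } else {
    stopifnot(inherits(base, "rate_matrix"), length(base$labels) == n)
    K <- base$transfer
    dimnames(K) <- NULL
    K[changed, ] <- 0
    K[, changed] <- 0
    touched <- upper.tri(V) & V != 0 &
      (row(V) %in% changed | col(V) %in% changed)
    pairs <- which(touched, arr.ind = TRUE)
  }
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    kk <- .pair_rates(pg, i, j, V[i, j], lineshape_library, temperature,
                      cache)
    K[i, j] <- kk[1]; K[j, i] <- kk[2]
  }
  rate_matrix(K, pg$kdecay_ps1, labels = pg$id, temperature = temperature)
}

#' Export / import a rate matrix
#'
#' CSV layout: one labeled row per pigment with its decay rate followed by
#' its outgoing transfer rates; JSON mirrors the object fields for run
#' manifests.
#'
#' @param rates A `rate_matrix`.
#' @param path Output file (`.csv` or `.json` by extension).
#' @return `write_rate_matrix` returns `path` invisibly; `read_rate_matrix`
#'   returns the `rate_matrix`.
#' @export
write_rate_matrix <- function(rates, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(labels = rates$labels, temperature = rates$temperature,
           decay = unname(rates$decay),
           transfer = unname(as.data.frame(rates$transfer))),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- data.frame(id = rates$labels, decay_ps1 = unname(rates$decay),
                     unname(as.data.frame(rates$transfer)))
    names(df)[-(1:2)] <- rates$labels
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_rate_matrix
#' @export
read_rate_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    rate_matrix(as.matrix(as.data.frame(x$transfer)), x$decay,
                labels = x$labels, temperature = x$temperature)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    rate_matrix(as.matrix(df[, -(1:2), drop = FALSE]), df$decay_ps1,
                labels = df$id)
  }
}
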