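# Electronic couplings between chromophore transitions: TrEsp from atomic
# transition charges, the point-dipole approximation for bilin-bilin pairs,
# assembly of the network coupling matrix, and the dipole fold-change metric.

#' TrEsp coupling between two transition-charge sets
#'
#' Coulomb sum over atom pairs, V = K * sum_ij q_i q_j / r_ij, with charges in
#' e, distances in Angstrom and K the vacuum conversion constant to cm^-1
#' (`physical_constants()$k_tresp`, about 1.1614e5 cm^-1 Angstrom e^-2).
#' Symmetric in its arguments.
#'
#' @param a,b `transition_charges` objects.
#' @param screening Dimensionless scaling of the vacuum interaction
#'   (default 1).
#' @return Coupling in cm^-1.
#' @export
tresp_coupling <- function(a, b, screening = 1) {
  stopifnot(inherits(a, "transition_charges"),
            inherits(b, "transition_charges"))
  # r2[i, j]: squared distance between atom i of a and atom j of b
  pa <- a$positions; pb <- b$positions
  r2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  r2[r2 < 0] <- 0
  if (any(r2 < 1e-12)) {
    ij <- which(r2 < 1e-12, arr.ind = TRUE)[1, ]
    stop("coincident atoms: atom ", ij[1], " of '", a$pigment_id,
         "' and atom ", ij[2], " of '", b$pigment_id,
         "' are at identical coordinates")
  }
  screening * .const$k_tresp * sum(outer(a$charges, b$charges) / sqrt(r2))
}

#' Orientation factor kappa of the point-dipole interaction
#'
#' kappa = u_a . u_b - 3 (u_a . R_hat)(u_b . R_hat); lies in [-2, 2] for unit
#' vectors.
#'
#' @param u_a,u_b Unit transition-dipole directions.
#' @param r_hat Unit vector from donor to acceptor.
#' @return Dimensionless orientation factor.
#' @export
orientation_factor <- function(u_a, u_b, r_hat) {
  sum(u_a * u_b) - 3 * sum(u_a * r_hat) * sum(u_b * r_hat)
}

#' Point-dipole coupling between two pigments
#'
#' V = screening * C * kappa * mu_a mu_b / R^3 with dipoles in debye, R in
#' Angstrom and C the vacuum constant `physical_constants()$c_pda`
#' (about 5034 cm^-1 Angstrom^3 D^-2).
#'
#' @param a,b Single rows of a pigment table (with `tdm_D` assigned).
#' @param screening Dimensionless screening factor (1 = vacuum).
#' @return Coupling in cm^-1.
#' @export
point_dipole_coupling <- function(a, b, screening = 1) {
  if (is.na(a$tdm_D) || is.na(b$tdm_D))
    stop("point-dipole coupling needs assigned tdm_D on both pigments")
  rvec <- c(b$x - a$x, b$y - a$y, b$z - a$z)
  r <- sqrt(sum(rvec^2))
  if (r < 1e-9) stop("coincident pigments: ", a$id, " and ", b$id)
  kap <- orientation_factor(c(a$ux, a$uy, a$uz), c(b$ux, b$uy, b$uz), rvec / r)
  screening * .const$c_pda * kap * a$tdm_D * b$tdm_D / r^3
}

#' Coupling rules for a pigment network
#'
#' Bilin-bilin (PCB-PCB) couplings always use the point-dipole approximation.
#' Carotenoid-bilin couplings exist only on the whitelisted pairs and come
#' either from TrEsp charge sets (`can_pcb_method = "TRESP"`) or from supplied
#' sampled values (`"SAMPLED"`); all other carotenoid couplings are exactly
#' zero.
#'
#' @param can_pcb_method `"TRESP"` or `"SAMPLED"`.
#' @param can_pcb_whitelist Two-column data.frame (`can_id`, `pcb_id`) of the
#'   pairs allowed a non-zero carotenoid coupling.
#' @param screening_factor Dimensionless screening for the PDA couplings
#'   (default 1, vacuum).
#' @return Object of class `coupling_rules`.
#' @export
coupling_rules <- function(can_pcb_method = c("SAMPLED", "TRESP"),
                           can_pcb_whitelist = NULL,
                           screening_factor = 1) {
  can_pcb_method <- match.arg(can_pcb_method)
  if (screening_factor <= 0) stop("screening_factor must be positive")
  if (is.null(can_pcb_whitelist))
    can_pcb_whitelist <- data.frame(can_id = character(),
                                    pcb_id = character(),
                                    stringsAsFactors = FALSE)
  stopifnot(all(c("can_id", "pcb_id") %in% names(can_pcb_whitelist)))
  structure(list(pcb_pcb_method = "PDA", can_pcb_method = can_pcb_method,
                 can_pcb_whitelist = can_pcb_whitelist,
                 screening_factor = screening_factor),
            class = "coupling_rules")
}

#' Assemble the full coupling matrix of a network
#'
#' PCB-PCB entries from the point-dipole approximation; whitelisted CAN-PCB
#' entries from TrEsp (when `rules$can_pcb_method == "TRESP"`, using `charges`)
#' or from `sampled` values; every non-whitelisted CAN pair is exactly zero
#' (neglected, not merely small). The result is symmetric with zero diagonal.
#'
#' @param network A `pigment_network` (couplings are overwritten).
#' @param rules A [coupling_rules()] object.
#' @param charges Named list, pigment id -> `transition_charges`; required for
#'   every whitelisted pair member in TRESP mode.
#' @param sampled Data.frame (`can_id`, `pcb_id`, `V_cm1`); required for every
#'   whitelisted pair in SAMPLED mode.
#' @return The network with its coupling matrix replaced.
#' @export
build_coupling_matrix <- function(network, rules, charges = NULL,
                                  sampled = NULL) {
  stopifnot(inherits(network, "pigment_network"),
            inherits(rules, "coupling_rules"))
  pg <- network$pigments
  n <- nrow(pg)
  V <- matrix(0, n, n, dimnames = list(pg$id, pg$id))
  wl <- rules$can_pcb_whitelist
  bad <- !(wl$can_id %in% pg$id) | !(wl$pcb_id %in% pg$id)
  if (any(bad))
    stop("whitelist references unknown pigment(s): ",
         paste(unique(c(wl$can_id[bad], wl$pcb_id[bad])), collapse = ", "))

  is_can <- pg$class == "CAN"
  pcb_idx <- which(!is_can)
  if (length(pcb_idx) > 1) {
    for (ii in seq_along(pcb_idx)[-length(pcb_idx)]) {
      i <- pcb_idx[ii]
      for (j in pcb_idx[(ii + 1):length(pcb_idx)]) {
        v <- point_dipole_coupling(pg[i, ], pg[j, ], rules$screening_factor)
        V[i, j] <- V[j, i] <- v
      }
    }
  }

  if (nrow(wl) > 0) {
    for (k in seq_len(nrow(wl))) {
      i <- match(wl$can_id[k], pg$id)
      j <- match(wl$pcb_id[k], pg$id)
      v <- if (rules$can_pcb_method == "TRESP") {
        ca <- charges[[wl$can_id[k]]]
        cb <- charges[[wl$pcb_id[k]]]
        if (is.null(ca) || is.null(cb))
          stop("TRESP mode: missing transition charges for pair (",
               wl$can_id[k], ", ", wl$pcb_id[k], ")")
        tresp_coupling(ca, cb)
      } else {
        sel <- sampled$can_id == wl$can_id[k] & sampled$pcb_id == wl$pcb_id[k]
        if (is.null(sampled) || sum(sel) != 1)
          stop("SAMPLED mode: no sampled coupling for pair (",
               wl$can_id[k], ", ", wl$pcb_id[k], ")")
        sampled$V_cm1[sel]
      }
      V[i, j] <- V[j, i] <- v
    }
  }
  network$couplings <- V
  network
}

#' Log fold change of a transition-dipole magnitude
#'
#' log(mu / mu_ref): the per-snapshot metric used to score how strongly a
#' perturbation (e.g. zeroing a side chain's charges) alters a transition
#' dipole. Negative values mean the perturbed dipole is smaller than the
#' reference.
#'
#' @param mu Perturbed dipole magnitude, debye (> 0).
#' @param mu_ref Reference dipole magnitude, debye (> 0).
#' @param base Logarithm base (default 10).
#' @return Dimensionless log ratio.
#' @export
#' @examples
#' tdm_fold_change(7, 7)       # 0
#' tdm_fold_change(7 / 3, 7)   # about -0.477: a threefold drop
tdm_fold_change <- function(mu, mu_ref, base = 10) {
  if (any(mu <= 0) || any(mu_ref <= 0))
    stop("dipole magnitudes must be positive")
  log(mu / mu_ref, base = base)
}

#' Export / import a coupling matrix as labeled CSV
#'
#' @param network A `pigment_network`.
#' @param path CSV path.
#' @return `write_coupling_csv` returns `path` invisibly; `read_coupling_csv`
#'   returns the labeled matrix.
#' @export
write_coupling_csv <- function(network, path) {
  utils::write.csv(network$couplings, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_coupling_csv
#' @export
read_coupling_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
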