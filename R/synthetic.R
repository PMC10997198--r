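# Synthetic phycobilisome-like pigment networks and carotenoid parameter
# samplers, so the full coupling/kinetics/dynamics stack runs with no
# external structure files. Geometry is an idealized surrogate: a
# tri-cylindrical allophycocyanin core with six radiating phycocyanin rods
# and four core-attached carotenoid quenchers; only the topology and the
# 10-30 Angstrom distance scales matter for testing the kinetics.

#' Configuration of the toy phycobilisome generator
#'
#' @param n_rods Number of rods radiating from the core (default 6).
#' @param pigments_per_rod Bilins per rod, spaced `nn_distance` apart.
#' @param core_cylinders Number of core cylinders (default 3: two basal, one
#'   top).
#' @param pigments_per_cylinder Bilins per core cylinder, arranged on two
#'   disks.
#' @param nn_distance Nearest-neighbour spacing along a rod, Angstrom.
#' @param n_can Number of carotenoid quenchers attached to the core
#'   (default 4).
#' @param can_attachment Optional data.frame (`can`, `pcb_id`) assigning each
#'   CAN's primary ApcA partner; default picks consecutive ApcA pigments.
#'   Attachment to a rod pigment is a configuration error (the carotenoid
#'   binds the core).
#' @param can_distance Distance from a CAN to its primary partner, Angstrom
#'   (default 12, within the 10-15 Angstrom contact range).
#' @param tdm_jitter_sd SD of the seeded angular jitter added to the
#'   tangential dipole directions.
#' @param seed Integer seed controlling jitter and any placement randomness.
#' @return List of class `toy_pbs_config`.
#' @export
toy_pbs_config <- function(n_rods = 6, pigments_per_rod = 6,
                           core_cylinders = 3, pigments_per_cylinder = 8,
                           nn_distance = 25, n_can = 4,
                           can_attachment = NULL, can_distance = 12,
                           tdm_jitter_sd = 0.1, seed = 1) {
  stopifnot(n_rods >= 0, pigments_per_rod >= 0, core_cylinders >= 1,
            core_cylinders <= 3, pigments_per_cylinder >= 2,
            nn_distance > 5, n_can >= 0, can_distance > 5)
  structure(list(n_rods = n_rods, pigments_per_rod = pigments_per_rod,
                 core_cylinders = core_cylinders,
                 pigments_per_cylinder = pigments_per_cylinder,
                 nn_distance = nn_distance, n_can = n_can,
                 can_attachment = can_attachment,
                 can_distance = can_distance,
                 tdm_jitter_sd = tdm_jitter_sd, seed = seed),
            class = "toy_pbs_config")
}

# unit vector with small seeded jitter
.jitter_unit <- function(u, sd) {
  v <- u + stats::rnorm(3, 0, sd)
  v / sqrt(sum(v^2))
}

#' Generate a toy phycobilisome pigment network
#'
#' Builds an idealized tri-cylindrical core (cylinder axes along x; two basal
#' cylinders side by side and one on top) of alternating ApcA/ApcB bilins
#' with one terminal ApcD and one ApcE emitter, six rods of phycocyanin
#' bilins radiating in the y-z plane, and `n_can` carotenoids placed
#' `can_distance` Angstrom outward from their primary ApcA partner. Dipole
#' directions are tangential with seeded jitter. Couplings: bilin-bilin by
#' the point-dipole approximation; each CAN coupled only to its two ApcA
#' partners at the supplied mean values (54 and 27 cm^-1 by default). The
#' network is deterministic for a given seed.
#'
#' @param config A [toy_pbs_config()].
#' @param scheme Site-property scheme; see [default_site_scheme()].
#' @param coupling_means Length-2 vector: CAN coupling to its rank-1 and
#'   rank-2 ApcA partner, cm^-1.
#' @param screening_factor Screening applied to the bilin-bilin point-dipole
#'   couplings.
#' @return A `pigment_network`; `metadata` records the config, seed and the
#'   CAN partner table (`can_pairs`).
#' @export
make_toy_pbs <- function(config = toy_pbs_config(),
                         scheme = default_site_scheme(),
                         coupling_means = c(54, 27),
                         screening_factor = 1) {
  stopifnot(inherits(config, "toy_pbs_config"))
  set.seed(config$seed)
  ids <- character(); cls <- character()
  pos <- NULL; tdm <- NULL

  # --- core cylinders -------------------------------------------------------
  centers <- list(B1 = c(-22, 0), B2 = c(22, 0), T1 = c(0, 38))
  centers <- centers[seq_len(config$core_cylinders)]
  radius <- 11
  npc <- config$pigments_per_cylinder
  for (cyl in names(centers)) {
    n1 <- ceiling(npc / 2)
    disk_x <- rep(c(-12.5, 12.5), times = c(n1, npc - n1))
    within <- c(seq_len(n1), seq_len(npc - n1))
    ndisk <- c(n1, npc - n1)[ifelse(seq_len(npc) <= n1, 1, 2)]
    ang <- 2 * pi * (within - 0.5) / ndisk
    cy <- centers[[cyl]][1]; cz <- centers[[cyl]][2]
    for (k in seq_len(npc)) {
      p <- c(disk_x[k], cy + radius * cos(ang[k]), cz + radius * sin(ang[k]))
      # tangent of the cylinder circle, jittered
      u <- .jitter_unit(c(0, -sin(ang[k]), cos(ang[k])), config$tdm_jitter_sd)
      cls_k <- if (k %% 2 == 1) "APCA_PCB" else "APCB_PCB"
      if (cyl == "B1" && k == 2) cls_k <- "APCD_PCB"
      if (cyl == "B2" && k == 2) cls_k <- "APCE_PCB"
      if (config$core_cylinders < 3 && cyl == "B1" && k == 4)
        cls_k <- "APCE_PCB"
      ids <- c(ids, sprintf("%s_%02d", cyl, k))
      cls <- c(cls, cls_k)
      pos <- rbind(pos, p); tdm <- rbind(tdm, u)
    }
  }

  # --- rods -----------------------------------------------------------------
  r0 <- 60
  for (rr in seq_len(config$n_rods)) {
    th <- 2 * pi * (rr - 1) / max(config$n_rods, 1)
    d <- c(0, cos(th), sin(th))
    for (m in seq_len(config$pigments_per_rod)) {
      p <- d * (r0 + (m - 1) * config$nn_distance)
      u <- .jitter_unit(c(0, -sin(th), cos(th)), config$tdm_jitter_sd)
      ids <- c(ids, sprintf("R%d_%02d", rr, m))
      cls <- c(cls, "ROD_PCB")
      pos <- rbind(pos, p); tdm <- rbind(tdm, u)
    }
  }

  # --- carotenoids ----------------------------------------------------------
  can_pairs <- NULL
  if (config$n_can > 0) {
    apca <- ids[cls == "APCA_PCB"]
    att <- config$can_attachment
    if (is.null(att)) {
      if (length(apca) < config$n_can)
        stop("not enough ApcA pigments (", length(apca),
             ") to attach ", config$n_can, " carotenoids")
      att <- data.frame(can = seq_len(config$n_can),
                        pcb_id = apca[seq_len(config$n_can)],
                        stringsAsFactors = FALSE)
    }
    if (!all(att$pcb_id %in% ids))
      stop("can_attachment references unknown pigment(s): ",
           paste(setdiff(att$pcb_id, ids), collapse = ", "))
    if (any(cls[match(att$pcb_id, ids)] == "ROD_PCB"))
      stop("carotenoids bind the core: attachment to a rod pigment (",
           paste(att$pcb_id[cls[match(att$pcb_id, ids)] == "ROD_PCB"],
                 collapse = ", "), ") is not allowed")
    for (k in seq_len(nrow(att))) {
      j <- match(att$pcb_id[k], ids)
      # outward from the cylinder axis at the partner's x
      cyl <- sub("_.*", "", att$pcb_id[k])
      ctr <- c(pos[j, 1], centers[[cyl]][1], centers[[cyl]][2])
      outward <- pos[j, ] - ctr
      outward <- outward / sqrt(sum(outward^2))
      p <- pos[j, ] + config$can_distance * outward
      cid <- sprintf("CAN_%d", k)
      ids <- c(ids, cid); cls <- c(cls, "CAN")
      pos <- rbind(pos, p)
      tdm <- rbind(tdm, .jitter_unit(c(1, 0, 0), config$tdm_jitter_sd))
      # rank-2 partner: the nearest other ApcA to the carotenoid
      others <- setdiff(apca, att$pcb_id[k])
      d2 <- apply(pos[match(others, ids), , drop = FALSE], 1,
                  function(q) sum((q - p)^2))
      can_pairs <- rbind(can_pairs,
                         data.frame(can_id = cid, pcb_id = att$pcb_id[k],
                                    rank = 1L),
                         data.frame(can_id = cid,
                                    pcb_id = others[which.min(d2)],
                                    rank = 2L))
    }
  }

  dmin <- min(stats::dist(pos))
  if (dmin <= 5)
    stop("generated geometry violates the 5 Angstrom minimum inter-pigment ",
         "distance (min ", signif(dmin, 3), ")")

  pg <- pigment_table(ids, cls, pos, tdm)
  pg <- assign_site_properties(pg, scheme)
  net <- pigment_network(pg, matrix(0, nrow(pg), nrow(pg)),
                         metadata = list(generator = "make_toy_pbs",
                                         config = unclass(config),
                                         seed = config$seed,
                                         can_pairs = can_pairs))
  wl <- if (is.null(can_pairs)) NULL else
    data.frame(can_id = can_pairs$can_id, pcb_id = can_pairs$pcb_id)
  sampled <- if (is.null(can_pairs)) NULL else
    data.frame(can_id = can_pairs$can_id, pcb_id = can_pairs$pcb_id,
               V_cm1 = coupling_means[can_pairs$rank])
  build_coupling_matrix(net,
                        coupling_rules("SAMPLED", can_pcb_whitelist = wl,
                                       screening_factor = screening_factor),
                        sampled = sampled)
}

#' Specification of the carotenoid parameter distributions
#'
#' Defaults follow the reported statistics for OCP-bound canthaxanthin: mean
#' vertical S0->S1 energy 2.00 eV and mean couplings 54 / 27 cm^-1 to the two
#' nearest ApcA bilins. Spreads are not printed anywhere tabulated, so they
#' are configuration: energy SD 0.07 eV and coupling SD 40% of the mean by
#' default. Draws are truncated at zero. `e00_shift_cm1` converts the sampled
#' vertical energy to the 0-0 site energy used for detailed balance (see the
#' vignette).
#'
#' @param e_s1_mean,e_s1_sd Vertical S1 energy mean and SD, eV.
#' @param coupling_means,coupling_sds Length-2: coupling to the rank-1/rank-2
#'   partner, cm^-1.
#' @param distribution `"truncated_normal"` or `"empirical_samples"`.
#' @param samples For the empirical mode: data.frame with columns `e_s1_eV`,
#'   `v1_cm1`, `v2_cm1` to resample from.
#' @param e00_shift_cm1 Vertical-to-0-0 shift, cm^-1 (default 1400, one
#'   dominant vibronic quantum).
#' @return List of class `can_parameter_spec`.
#' @export
can_parameter_spec <- function(e_s1_mean = 2.00, e_s1_sd = 0.07,
                               coupling_means = c(54, 27),
                               coupling_sds = 0.4 * coupling_means,
                               distribution = c("truncated_normal",
                                                "empirical_samples"),
                               samples = NULL,
                               e00_shift_cm1 = 1400) {
  distribution <- match.arg(distribution)
  stopifnot(e_s1_mean > 0, e_s1_sd >= 0, all(coupling_means > 0),
            all(coupling_sds >= 0), length(coupling_means) == 2,
            length(coupling_sds) == 2)
  if (distribution == "empirical_samples" &&
      (is.null(samples) || nrow(samples) == 0))
    stop("empirical_samples mode requires a non-empty samples table")
  structure(list(e_s1_mean = e_s1_mean, e_s1_sd = e_s1_sd,
                 coupling_means = coupling_means,
                 coupling_sds = coupling_sds,
                 distribution = distribution, samples = samples,
                 e00_shift_cm1 = e00_shift_cm1),
            class = "can_parameter_spec")
}

# truncated-normal draw on (0, Inf) by inverse-CDF; exact, no rejection
.rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  stats::qnorm(stats::runif(n, stats::pnorm(0, mean, sd), 1), mean, sd)
}

#' Sample carotenoid parameters
#'
#' Independent draws of (vertical S1 energy, rank-1 coupling, rank-2
#' coupling) per carotenoid, truncated to positive support.
#'
#' @param spec A [can_parameter_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Optional seed; `NULL` uses the current RNG stream (as
#'   [run_ensemble()] does, so ensembles stay a pure function of the master
#'   seed).
#' @return Data.frame `e_s1_eV`, `v1_cm1`, `v2_cm1` with `n` rows.
#' @export
sample_can_parameters <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "can_parameter_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (spec$distribution == "empirical_samples") {
    idx <- sample.int(nrow(spec$samples), n, replace = TRUE)
    out <- spec$samples[idx, c("e_s1_eV", "v1_cm1", "v2_cm1")]
    rownames(out) <- NULL
    return(out)
  }
  data.frame(
    e_s1_eV = .rtnorm_pos(n, spec$e_s1_mean, spec$e_s1_sd),
    v1_cm1 = .rtnorm_pos(n, spec$coupling_means[1], spec$coupling_sds[1]),
    v2_cm1 = .rtnorm_pos(n, spec$coupling_means[2], spec$coupling_sds[2])
  )
}

#' Write a minimal synthetic structure fixture
#'
#' Writes a small, valid mmCIF (or PDB) file containing a known number of
#' bilin-like (code CYC) and carotenoid-like (code CAN) HETATM cofactors with
#' known conjugated-atom geometry, for exercising [read_structure()] without
#' any downloaded structure. The file is synthetic and carries no real
#' coordinates.
#'
#' @param path Output path.
#' @param n_bilin,n_can Cofactor counts.
#' @param atoms_per_cofactor Atoms per cofactor (>= 3), laid out on a line
#'   with a small fixed perpendicular offset on the middle atom so the
#'   geometry is not exactly degenerate.
#' @param format `"cif"` or `"pdb"`.
#' @return `path`, invisibly. Bilin axes are along x; carotenoid axes along
#'   y.
#' @export
make_fixture_structure <- function(path, n_bilin = 3, n_can = 1,
                                   atoms_per_cofactor = 5,
                                   format = c("cif", "pdb")) {
  format <- match.arg(format)
  stopifnot(atoms_per_cofactor >= 3)
  recs <- list(); serial <- 0L
  add <- function(code, chain, resno, origin, axis) {
    for (a in seq_len(atoms_per_cofactor)) {
      serial <<- serial + 1L
      p <- origin + (a - 1) * 1.5 * axis
      if (a == ceiling(atoms_per_cofactor / 2))
        p <- p + c(0, 0, 0.3)  # break exact collinearity
      recs[[length(recs) + 1L]] <<- list(
        serial = serial, name = paste0("C", a), code = code, chain = chain,
        resno = resno, x = p[1], y = p[2], z = p[3])
    }
  }
  for (b in seq_len(n_bilin))
    add("CYC", LETTERS[b], b, c(0, (b - 1) * 20, 0), c(1, 0, 0))
  for (k in seq_len(n_can))
    add("CAN", LETTERS[n_bilin + k], n_bilin + k,
        c(40, (k - 1) * 20, 0), c(0, 1, 0))

  if (format == "cif") {
    hdr <- c("data_synthetic_fixture", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    lines <- vapply(recs, function(r) sprintf(
      "HETATM %d C %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
      r$serial, r$name, r$code, r$chain, r$resno, r$x, r$y, r$z,
      r$resno, r$code, r$chain, r$name), "")
    writeLines(c(hdr, lines, "#"), path)
  } else {
    lines <- vapply(recs, function(r) sprintf(
      "HETATM%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      r$serial, r$name, r$code, r$chain, r$resno, r$x, r$y, r$z), "")
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}
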