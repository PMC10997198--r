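# Transition-charge sets: atomic point charges representing one electronic
# transition, the input of the TrEsp coupling method.

#' Construct a transition-charge set
#'
#' Transition charges of a dipole-allowed transition integrate to zero total
#' charge; the constructor enforces this within `sum_tolerance` (set it to
#' `Inf` for deliberately unbalanced toy sets). If `declared_tdm_D` is given,
#' the dipole of the charges (sum of q_i r_i, converted to debye) must match
#' it within relative tolerance `tdm_rtol`.
#'
#' @param pigment_id Identifier of the pigment the transition belongs to.
#' @param positions n x 3 matrix of atom coordinates, Angstrom.
#' @param charges Numeric vector of length n, units of elementary charge e.
#' @param sum_tolerance Allowed absolute total charge, e (default 1e-3).
#' @param declared_tdm_D Optional transition-dipole magnitude to check
#'   against, debye.
#' @param tdm_rtol Relative tolerance for the declared-dipole check.
#' @return Object of class `transition_charges`.
#' @export
transition_charges <- function(pigment_id, positions, charges,
                               sum_tolerance = 1e-3,
                               declared_tdm_D = NULL, tdm_rtol = 0.05) {
  positions <- rbind(positions)
  charges <- as.numeric(charges)
  if (nrow(positions) != length(charges))
    stop("positions (", nrow(positions), ") and charges (", length(charges),
         ") must have equal lengths")
  if (abs(sum(charges)) > sum_tolerance)
    stop("transition charges sum to ", signif(sum(charges), 3),
         " e, exceeding tolerance ", sum_tolerance,
         " e; transition charges of an allowed transition are net neutral")
  obj <- structure(list(pigment_id = as.character(pigment_id),
                        positions = positions, charges = charges),
                   class = "transition_charges")
  if (!is.null(declared_tdm_D)) {
    mu <- tcs_dipole_debye(obj)
    if (abs(mu - declared_tdm_D) > tdm_rtol * abs(declared_tdm_D))
      stop("charge-set dipole (", signif(mu, 4), " D) deviates from declared ",
           declared_tdm_D, " D by more than ", tdm_rtol * 100, "%")
  }
  obj
}

#' Transition dipole of a charge set, in debye
#'
#' Magnitude of sum(q_i * r_i) with q in e and r in Angstrom, converted to
#' debye (1 e Angstrom ~ 4.8032 D).
#'
#' @param tcs A `transition_charges` object.
#' @return Dipole magnitude, debye.
#' @export
tcs_dipole_debye <- function(tcs) {
  mu <- colSums(tcs$positions * tcs$charges)
  sqrt(sum(mu^2)) * .const$eA_debye
}

#' Read a transition-charge table from text
#'
#' Expected format: whitespace- or comma-separated columns with a header line
#' `atom x y z q` (coordinates in Angstrom, charges in e).
#'
#' @param path Path to the table.
#' @param pigment_id Pigment the charges belong to (defaults to the file
#'   base name).
#' @param ... Passed on to [transition_charges()] (e.g. `sum_tolerance`).
#' @return Object of class `transition_charges`.
#' @export
read_charge_table <- function(path, pigment_id = NULL, ...) {
  if (!file.exists(path)) stop("charge table not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("atom", "x", "y", "z", "q")
  if (!all(need %in% names(df)))
    stop("charge table must have columns: ", paste(need, collapse = ", "))
  if (is.null(pigment_id))
    pigment_id <- tools::file_path_sans_ext(basename(path))
  transition_charges(pigment_id, as.matrix(df[, c("x", "y", "z")]), df$q, ...)
}

#' Write a transition-charge table
#'
#' @param tcs A `transition_charges` object.
#' @param path Output path.
#' @param atom_names Optional atom labels (default `A1..An`).
#' @return `path`, invisibly.
#' @export
write_charge_table <- function(tcs, path, atom_names = NULL) {
  n <- length(tcs$charges)
  if (is.null(atom_names)) atom_names <- paste0("A", seq_len(n))
  df <- data.frame(atom = atom_names, x = tcs$positions[, 1],
                   y = tcs$positions[, 2], z = tcs$positions[, 3],
                   q = tcs$charges)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
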