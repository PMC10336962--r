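.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default intrinsic pKa table and hydropathy scale
#'
#' `default_pka()` loads the packaged intrinsic pKa values (Nozaki-Tanford)
#' used for fixed-charge assignment; `kyte_doolittle()` the per-residue
#' Kyte-Doolittle hydropathy scale. Both ship as editable YAML under
#' `inst/extdata/` so users can substitute their own tables.
#'
#' @return `default_pka()`: a list with elements `residues` (named list of
#'   `pka`/`type` pairs, `type` in `"acid"`/`"base"`) and `termini`
#'   (`n_terminus`, `c_terminus`). `kyte_doolittle()`: a named numeric
#'   vector over the 20 standard residues.
#' @export
default_pka <- function() yaml::read_yaml(.extdata("pka_nozaki_tanford.yaml"))

#' @rdname default_pka
#' @export
kyte_doolittle <- function() {
  unlist(yaml::read_yaml(.extdata("kyte_doolittle.yaml")))
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% .AA)
  if (length(bad))
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  res
}

# Henderson-Hasselbalch mean charge of one titratable site
.hh_charge <- function(pka, type, pH) {
  switch(type,
         base = 1 / (1 + 10^(pH - pka)),
         acid = -1 / (1 + 10^(pka - pH)),
         stop("pKa entry type must be 'acid' or 'base'"))
}

# round to the dominant protonation state: {-1, 0, +1}
.hh_round <- function(q) as.integer(sign(q) * (abs(q) >= 0.5))

#' Assign fixed integer charges to a bead chain
#'
#' Maps each residue of a protein sequence to a fixed charge in
#' \{-1, 0, +1\}, the charge resolution of the bead-necklace model. Each
#' titratable site receives the sign of its dominant protonation state at the
#' given pH under the Henderson-Hasselbalch equation with intrinsic pKa
#' values (mean site charge of magnitude >= 0.5 rounds away from zero,
#' otherwise the bead is neutral). The assignment is deterministic.
#'
#' Chain termini are titratable too. With `termini_mode = "merged"` (default)
#' the terminal charges are added onto the first and last residue beads and
#' the sums clamped to \{-1, 0, +1\} (with a warning when clamping occurs);
#' `"extra_beads"` instead prepends/appends two dedicated terminal beads.
#'
#' @param sequence one-letter amino-acid string (20 standard residues)
#' @param pH solution pH in \[0, 14\] (default 7)
#' @param pka_table intrinsic pKa table in the format of [default_pka()]
#' @param termini_mode `"merged"` or `"extra_beads"`, see Details
#' @return a `charge_assignment`: list with `per_bead_charge` (integer
#'   vector, one per bead), `net_charge`, `n_positive`, `n_negative`,
#'   `termini_mode`, `pH`
#' @examples
#' ca <- assign_charges("GGGGG")          # only the termini titrate
#' ca$per_bead_charge                     # +1 0 0 0 -1
#' @export
assign_charges <- function(sequence, pH = 7, pka_table = default_pka(),
                           termini_mode = c("merged", "extra_beads")) {
  termini_mode <- match.arg(termini_mode)
  res <- .check_sequence(sequence)
  if (!is.numeric(pH) || length(pH) != 1L || pH < 0 || pH > 14)
    stop("pH must be a single value in [0, 14]")

  titratable <- names(pka_table$residues)
  present <- unique(res[res %in% c("D", "E", "H", "C", "Y", "K", "R")])
  missing <- setdiff(present, titratable)
  if (length(missing))
    stop("pKa table is missing titratable residue(s): ",
         paste(missing, collapse = ", "))

  q <- integer(length(res))
  for (r in intersect(titratable, unique(res))) {
    entry <- pka_table$residues[[r]]
    q[res == r] <- .hh_round(.hh_charge(entry$pka, entry$type, pH))
  }
  qn <- .hh_round(.hh_charge(pka_table$termini$n_terminus$pka,
                             pka_table$termini$n_terminus$type, pH))
  qc <- .hh_round(.hh_charge(pka_table$termini$c_terminus$pka,
                             pka_table$termini$c_terminus$type, pH))

  if (termini_mode == "merged") {
    n <- length(q)
    q[1] <- q[1] + qn
    q[n] <- q[n] + qc
    if (any(abs(q[c(1, n)]) > 1L)) {
      warning("terminal charge clamped to +/-1 after merging")
      q[1] <- max(-1L, min(1L, q[1]))
      q[n] <- max(-1L, min(1L, q[n]))
    }
  } else {
    q <- c(qn, q, qc)
  }

  structure(list(per_bead_charge = as.integer(q),
                 net_charge = as.integer(sum(q)),
                 n_positive = sum(q > 0L),
                 n_negative = sum(q < 0L),
                 termini_mode = termini_mode,
                 pH = pH),
            class = "charge_assignment")
}

#' @export
print.charge_assignment <- function(x, ...) {
  cat("Bead charge assignment (pH ", x$pH, ", termini ", x$termini_mode,
      "): ", length(x$per_bead_charge), " beads, net ",
      sprintf("%+d", x$net_charge), " (", x$n_positive, " positive, ",
      x$n_negative, " negative)\n", sep = "")
  invisible(x)
}

#' Sequence composition descriptors
#'
#' Computes the descriptors used in the property-bias analysis: fraction of
#' charged residues FCR = f+ + f-, net charge per residue
#' NCPR = |f+ - f-|, mean Kyte-Doolittle hydropathy, and proline fraction.
#' Residue charges come from the same Henderson-Hasselbalch rounding as
#' [assign_charges()]; chain termini are excluded from the charge fractions.
#'
#' @inheritParams assign_charges
#' @param disorder_score optional externally computed disorder score in
#'   \[0, 1\] carried through unchanged (the package does not predict
#'   disorder)
#' @return list with `fcr`, `ncpr`, `kd_hydrophobicity`, `proline_fraction`,
#'   `f_plus`, `f_minus`, and `disorder_score`
#' @examples
#' d <- sequence_descriptors("KKDAAAAAAG")
#' d$fcr   # 0.3
#' d$ncpr  # 0.1
#' @export
sequence_descriptors <- function(sequence, pH = 7,
                                 pka_table = default_pka(),
                                 disorder_score = NA_real_) {
  res <- .check_sequence(sequence)
  n <- length(res)
  q <- integer(n)
  for (r in intersect(names(pka_table$residues), unique(res))) {
    entry <- pka_table$residues[[r]]
    q[res == r] <- .hh_round(.hh_charge(entry$pka, entry$type, pH))
  }
  f_plus <- sum(q > 0L) / n
  f_minus <- sum(q < 0L) / n
  kd <- kyte_doolittle()
  list(fcr = f_plus + f_minus,
       ncpr = abs(f_plus - f_minus),
       kd_hydrophobicity = mean(kd[res]),
       proline_fraction = sum(res == "P") / n,
       f_plus = f_plus,
       f_minus = f_minus,
       disorder_score = disorder_score)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [seqinr::read.fasta()] that upper-cases sequences,
#' normalizes line wrapping and preserves record order.
#'
#' @param path FASTA file with one or more records
#' @return named character vector of sequences, in file order
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("could not parse FASTA file: ",
                             conditionMessage(e)))
  if (!length(recs)) stop("FASTA file contains no records: ", path)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  seqs <- gsub("[[:space:]]", "", seqs)
  if (any(!nzchar(seqs)))
    stop("FASTA record with empty sequence: ",
         paste(names(recs)[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs
}
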