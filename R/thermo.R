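#' Load a nearest-neighbor parameter table for RNA/DNA hybrid duplexes
#'
#' Reads a TSV with columns `step`, `dH_kcal`, `dS_cal`, `dG37_kcal`
#' holding the 16 dinucleotide parameters plus one `INIT` row for helix
#' initiation. Steps are keyed by the RNA strand read 5'->3'; the DNA
#' strand is implied by complementarity. The packaged default transcribes
#' the Sugimoto et al. (1995) RNA/DNA hybrid set. On load the table is
#' checked for internal consistency: `dG37 = dH - (310.15 * dS)/1000`
#' must hold within 0.1 kcal/mol for every entry.
#'
#' @param path TSV path; defaults to the packaged parameter file.
#' @return An object of class `nn_table`: list with `steps` (data frame of
#'   16 rows, rownames = RNA dinucleotide) and `init` (named numeric
#'   `dH`, `dS`, `dG37`).
#' @references Sugimoto N. et al. (1995) Biochemistry 34:11211-11216.
#' @export
nn_table <- function(path = system.file("extdata", "sugimoto1995_rna_dna_nn.tsv",
                                        package = "crossmir")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("step", "dH_kcal", "dS_cal", "dG37_kcal")
  if (!all(need %in% names(tab)))
    stop("parameter file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  init_row <- tab$step == "INIT"
  if (sum(init_row) != 1L)
    stop("parameter file must contain exactly one INIT row", call. = FALSE)
  init <- c(dH = tab$dH_kcal[init_row], dS = tab$dS_cal[init_row],
            dG37 = tab$dG37_kcal[init_row])
  steps <- tab[!init_row, , drop = FALSE]
  dinucs <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                            paste0))
  if (nrow(steps) != 16L || !setequal(steps$step, dinucs))
    stop("parameter table must contain exactly the 16 RNA dinucleotide steps",
         call. = FALSE)
  rownames(steps) <- steps$step
  dev <- abs(steps$dH_kcal - 310.15 * steps$dS_cal / 1000 - steps$dG37_kcal)
  if (any(dev > 0.1))
    stop("inconsistent entry (dG37 != dH - T*dS at 310.15 K): ",
         paste(steps$step[dev > 0.1], collapse = ", "), call. = FALSE)
  structure(list(steps = steps, init = init, path = path), class = "nn_table")
}

#' Hybridization conditions for melting-temperature prediction
#'
#' Bundles the constants of the two-state Tm formula. Defaults are the
#' standard stringent-hybridization conditions used for the packaged probe
#' panel: 1 M Na+, 100 uM total strand concentration, helix initiation
#' factor A = -10.8 cal/(K mol), 0.63 degC depression per percent formamide
#' at 35% formamide, and R = 1.987 cal/(K mol).
#'
#' @param na_molar Sodium concentration, mol/L.
#' @param ct_molar Total oligonucleotide concentration, mol/L.
#' @param a_init Helix initiation factor, cal/(K mol), entering the Tm
#'   denominator.
#' @param f_formamide Tm depression per 1% formamide, degC.
#' @param formamide_pct Formamide concentration, percent.
#' @param r_gas Gas constant, cal/(K mol).
#' @return An object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(na_molar = 1.0, ct_molar = 1e-4, a_init = -10.8,
                              f_formamide = 0.63, formamide_pct = 35,
                              r_gas = 1.987) {
  stopifnot(na_molar > 0, ct_molar > 0, f_formamide >= 0,
            formamide_pct >= 0, r_gas > 0)
  structure(list(na_molar = na_molar, ct_molar = ct_molar, a_init = a_init,
                 f_formamide = f_formamide, formamide_pct = formamide_pct,
                 r_gas = r_gas),
            class = "thermo_conditions")
}

#' Align a miRNA and its probe into an RNA/DNA duplex
#'
#' The probe (its base sequence, or base plus optional tail) must be the
#' contiguous reverse complement of a 3'-anchored segment of the mature
#' miRNA — full-length probes cover the whole miRNA, shorter probes its 3'
#' end; a probe tail extends the covered window one base toward the miRNA
#' 5' end. Any mismatch inside the paired region is an error identifying
#' the first mismatched position (1 = 5' end of the paired RNA window).
#'
#' @param rna RNA [sequence_record()] (the mature miRNA).
#' @param probe A [probe_record()] or DNA `sequence_record`.
#' @param with_tail Include the probe's optional tail, if present.
#' @return An object of class `hybrid_duplex`: the covered RNA window, its
#'   offset in the miRNA, and the ordered RNA-strand dinucleotide steps
#'   (paired length − 1 of them).
#' @export
pair_probe <- function(rna, probe, with_tail = TRUE) {
  stopifnot(inherits(rna, "sequence_record"))
  if (rna$alphabet != "RNA") stop("'rna' must be an RNA record", call. = FALSE)
  if (inherits(probe, "sequence_record")) probe <- probe_record(probe)
  stopifnot(inherits(probe, "probe_record"))
  pseq <- probe_seq(probe, with_tail = with_tail)
  k <- nchar(pseq)
  n <- seq_length(rna)
  if (k < 2L)
    stop("probe must pair at least 2 nucleotides", call. = FALSE)
  if (k > n)
    stop(sprintf("probe '%s' (%d nt) is longer than target '%s' (%d nt)",
                 probe$base$name, k, rna$name, n), call. = FALSE)
  target <- reverse_complement(
    sequence_record(probe$base$name, pseq, "DNA"), "RNA")$seq
  window <- substr(rna$seq, n - k + 1L, n)
  if (window != target) {
    wb <- strsplit(window, "")[[1L]]
    tb <- strsplit(target, "")[[1L]]
    pos <- which(wb != tb)[1L]
    stop(sprintf(
      "probe '%s' mismatches target '%s' at duplex position %d (RNA %s vs probe-implied %s)",
      probe$base$name, rna$name, pos, wb[pos], tb[pos]), call. = FALSE)
  }
  steps <- substring(window, 1L:(k - 1L), 2L:k)
  structure(list(mirna = rna$name, probe = probe$base$name, window = window,
                 offset = n - k + 1L, steps = steps),
            class = "hybrid_duplex")
}

#' @export
print.hybrid_duplex <- function(x, ...) {
  cat(sprintf("RNA/DNA duplex %s::%s, %d paired nt (%d steps), RNA window %s\n",
              x$mirna, x$probe, nchar(x$window), length(x$steps), x$window))
  invisible(x)
}

nn_lookup <- function(duplex, nn, col) {
  missing <- setdiff(unique(duplex$steps), rownames(nn$steps))
  if (length(missing))
    stop("no nearest-neighbor entry for step(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  nn$steps[duplex$steps, col]
}

#' Duplex free energy at 37 degC
#'
#' Sums the per-step dG37 values over the duplex's RNA-strand dinucleotide
#' steps and adds the table's initiation dG37. More negative means a more
#' stable hybrid. Additivity holds by construction: removing one terminal
#' step changes the result by exactly that step's parameter.
#'
#' @param duplex A [pair_probe()] result.
#' @param nn A [nn_table()].
#' @return Free energy in kcal/mol.
#' @export
hybrid_delta_g <- function(duplex, nn = nn_table()) {
  stopifnot(inherits(duplex, "hybrid_duplex"), inherits(nn, "nn_table"))
  if (length(duplex$steps) < 1L) stop("duplex has no steps", call. = FALSE)
  sum(nn_lookup(duplex, nn, "dG37_kcal")) + nn$init[["dG37"]]
}

#' Duplex melting temperature under the two-state model
#'
#' Computes
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S + A + R\ln(C_t/4)} - 273.15
#'   + 16.6\log_{10}[\mathrm{Na}^+] - F \cdot \%\mathrm{formamide}}
#' with \eqn{\Delta H} (kcal/mol) and \eqn{\Delta S} (cal/(K mol)) summed
#' over the duplex's nearest-neighbor steps. By default the parameter
#' table's helix-initiation enthalpy and entropy are included in the sums
#' in addition to the condition constant `A` in the denominator
#' (`include_initiation = TRUE`); this calibration reproduces reference
#' melting temperatures for full-length probe panels (see the methods
#' vignette). `Ct/4` is the non-self-complementary two-state convention;
#' the salt term vanishes at 1 M Na+.
#'
#' @param duplex A [pair_probe()] result.
#' @param nn A [nn_table()].
#' @param cond A [thermo_conditions()].
#' @param include_initiation Include the table's initiation dH/dS in the
#'   enthalpy and entropy sums.
#' @return Melting temperature in degC.
#' @export
hybrid_tm <- function(duplex, nn = nn_table(), cond = thermo_conditions(),
                      include_initiation = TRUE) {
  stopifnot(inherits(duplex, "hybrid_duplex"), inherits(nn, "nn_table"),
            inherits(cond, "thermo_conditions"))
  if (length(duplex$steps) < 1L) stop("duplex has no steps", call. = FALSE)
  dH <- sum(nn_lookup(duplex, nn, "dH_kcal"))
  dS <- sum(nn_lookup(duplex, nn, "dS_cal"))
  if (include_initiation) {
    dH <- dH + nn$init[["dH"]]
    dS <- dS + nn$init[["dS"]]
  }
  denom <- dS + cond$a_init + cond$r_gas * log(cond$ct_molar / 4)
  if (denom >= 0)
    stop("unphysical duplex: non-negative Tm denominator", call. = FALSE)
  1000 * dH / denom - 273.15 + 16.6 * log10(cond$na_molar) -
    cond$f_formamide * cond$formamide_pct
}

thermo_result <- function(duplex, nn, cond, include_initiation = TRUE) {
  dH <- sum(nn_lookup(duplex, nn, "dH_kcal"))
  dS <- sum(nn_lookup(duplex, nn, "dS_cal"))
  if (include_initiation) {
    dH <- dH + nn$init[["dH"]]
    dS <- dS + nn$init[["dS"]]
  }
  structure(list(mirna = duplex$mirna, probe = duplex$probe,
                 paired_nt = nchar(duplex$window),
                 dG37 = hybrid_delta_g(duplex, nn), dH = dH, dS = dS,
                 tm = hybrid_tm(duplex, nn, cond, include_initiation)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("%s::%s  %d nt paired  dG37 %.1f kcal/mol  Tm %.1f degC\n",
              x$mirna, x$probe, x$paired_nt, x$dG37, x$tm))
  invisible(x)
}

#' Thermodynamics for a probe and its optional-tail variant
#'
#' When the probe carries an optional 3' tail base, two duplexes exist: the
#' extended probe (base + tail) and the core probe (base only). Results are
#' returned for both, extended first; a probe without a tail yields a
#' single result.
#'
#' @inheritParams pair_probe
#' @param nn A [nn_table()].
#' @param cond A [thermo_conditions()].
#' @param include_initiation See [hybrid_tm()].
#' @return A list of one or two `thermo_result` objects, named
#'   `"extended"` and `"core"` (or just `"core"`).
#' @export
probe_variants <- function(rna, probe, nn = nn_table(),
                           cond = thermo_conditions(),
                           include_initiation = TRUE) {
  if (inherits(probe, "sequence_record")) probe <- probe_record(probe)
  out <- list()
  if (!is.null(probe$optional_tail)) {
    out$extended <- thermo_result(pair_probe(rna, probe, with_tail = TRUE),
                                  nn, cond, include_initiation)
  }
  out$core <- thermo_result(pair_probe(rna, probe, with_tail = FALSE),
                            nn, cond, include_initiation)
  out
}
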