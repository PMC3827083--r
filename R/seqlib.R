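#' Create a nucleotide sequence record
#'
#' A `sequence_record` is the basic unit handled by the probe-thermodynamics
#' and panel-report functions: a named, uppercase nucleotide string with a
#' declared alphabet. Input is uppercased on ingest; a base that is illegal
#' for the declared alphabet is rejected (in particular, `T` in an
#' RNA-declared sequence is an error, never silently converted).
#'
#' @param name Identifier, a non-empty string.
#' @param seq Nucleotide string. RNA may contain only A/C/G/U, DNA only
#'   A/C/G/T. Lowercase input is accepted and uppercased.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return An object of class `sequence_record` with fields `name`, `seq`
#'   and `alphabet`.
#' @examples
#' sequence_record("mmu-miR-322", "CAGCAGCAAUUCAUGUUUUGGA", "RNA")
#' @export
sequence_record <- function(name, seq, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("sequence for '", name, "' must be a non-empty string", call. = FALSE)
  seq <- toupper(seq)
  allowed <- if (alphabet == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!bases %in% allowed)
  if (length(bad))
    stop(sprintf("invalid %s base '%s' at position %d in '%s'",
                 alphabet, bases[bad[1L]], bad[1L], name), call. = FALSE)
  structure(list(name = name, seq = seq, alphabet = alphabet),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<%s> %s (%d nt, %s)\n", x$alphabet, x$name, nchar(x$seq), x$seq))
  invisible(x)
}

seq_length <- function(rec) nchar(rec$seq)

#' Create a microarray probe record
#'
#' A probe is a DNA oligonucleotide, optionally carrying a single extra base
#' appended at its 3' end. Some array designs print such probes with the
#' terminal residue parenthesized, e.g. `"CACAAACCATTATGTGCTGCT(A)"`,
#' meaning the probe is synthesised both with and without that base;
#' [probe_variants()] evaluates both duplexes.
#'
#' @param base A DNA [sequence_record()], or a plain string (then `name`
#'   must be given).
#' @param optional_tail `NULL`, or a single DNA base appended at the 3' end.
#' @param name Probe name when `base` is a plain string.
#' @return An object of class `probe_record`.
#' @seealso [parse_probe()] for the parenthesized text form.
#' @export
probe_record <- function(base, optional_tail = NULL, name = NULL) {
  if (!inherits(base, "sequence_record")) {
    if (is.null(name)) stop("'name' is required when 'base' is a string", call. = FALSE)
    base <- sequence_record(name, base, "DNA")
  }
  if (base$alphabet != "DNA")
    stop("probe base sequence must be DNA", call. = FALSE)
  if (!is.null(optional_tail)) {
    optional_tail <- toupper(optional_tail)
    if (!is.character(optional_tail) || length(optional_tail) != 1L ||
        nchar(optional_tail) != 1L || !optional_tail %in% c("A", "C", "G", "T"))
      stop("'optional_tail' must be a single DNA base", call. = FALSE)
  }
  structure(list(base = base, optional_tail = optional_tail),
            class = "probe_record")
}

#' Parse a probe written with a parenthesized optional tail
#'
#' Converts text such as `"ACACCGAGGAGCC(C)"` into a [probe_record()] whose
#' `optional_tail` is the parenthesized base. Text without parentheses gives
#' a probe with no tail.
#'
#' @param text Probe string, optionally ending in `(X)`.
#' @param name Probe name.
#' @return A `probe_record`.
#' @export
parse_probe <- function(text, name) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  m <- regmatches(text, regexec("^([ACGTacgt]+)(?:\\(([ACGTacgt])\\))?$", text))[[1L]]
  if (length(m) == 0L)
    stop("cannot parse probe text '", text, "'", call. = FALSE)
  tail <- if (nzchar(m[3L])) m[3L] else NULL
  probe_record(sequence_record(name, m[2L], "DNA"), optional_tail = tail)
}

probe_seq <- function(probe, with_tail = TRUE) {
  s <- probe$base$seq
  if (with_tail && !is.null(probe$optional_tail)) s <- paste0(s, probe$optional_tail)
  s
}

#' GC content of a sequence, as a truncated integer percentage
#'
#' Returns `100 * (#G + #C) / length`, truncated toward zero to an integer.
#' Truncation (rather than rounding) is the convention used throughout the
#' package's probe-panel reports; e.g. 12/22 = 54.55% reports as 54.
#' GC content is invariant under reverse complementation.
#'
#' @param rec A [sequence_record()].
#' @return Integer percent in 0..100.
#' @examples
#' gc_content(sequence_record("mmu-miR-433", "AUCAUGAUGGGCUCCUCGGUGU", "RNA")) # 54
#' @export
gc_content <- function(rec) {
  stopifnot(inherits(rec, "sequence_record"))
  bases <- strsplit(rec$seq, "", fixed = TRUE)[[1L]]
  as.integer(floor(100 * sum(bases %in% c("G", "C")) / length(bases)))
}

COMPLEMENT <- list(
  RNA = c(A = "U", C = "G", G = "C", U = "A"),
  DNA = c(A = "T", C = "G", G = "C", T = "A")
)

#' Watson-Crick reverse complement, optionally crossing alphabets
#'
#' Computes the reverse complement of a sequence record in the requested
#' output alphabet, with U/A pairing when crossing between RNA and DNA
#' (an RNA target's complementary DNA probe is
#' `reverse_complement(rna, "DNA")`).
#'
#' @param rec A [sequence_record()].
#' @param out_alphabet Alphabet of the result; defaults to the input's.
#' @return A `sequence_record` named `<name>_rc`.
#' @export
reverse_complement <- function(rec, out_alphabet = rec$alphabet) {
  stopifnot(inherits(rec, "sequence_record"))
  out_alphabet <- match.arg(out_alphabet, c("RNA", "DNA"))
  bases <- strsplit(rec$seq, "", fixed = TRUE)[[1L]]
  # complement in the input alphabet, then transliterate T<->U if crossing
  comp <- COMPLEMENT[[rec$alphabet]][bases]
  if (out_alphabet != rec$alphabet) {
    comp <- if (out_alphabet == "DNA") sub("U", "T", comp) else sub("T", "U", comp)
  }
  sequence_record(paste0(rec$name, "_rc"),
                  paste(rev(comp), collapse = ""), out_alphabet)
}

infer_alphabet <- function(seq) {
  if (grepl("U", seq, fixed = TRUE)) "RNA"
  else if (grepl("T", seq, fixed = TRUE)) "DNA"
  else "RNA"
}

#' Read sequence records from FASTA or TSV
#'
#' FASTA is read with `Biostrings::readBStringSet()`; the alphabet of each
#' record is taken from `alphabet` if supplied, otherwise inferred (U
#' present: RNA; T present: DNA; neither: RNA). The TSV format is a
#' three-column table with header `name`, `sequence`, `alphabet`; malformed
#' TSV rows raise an error naming the offending line.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @param alphabet Optional alphabet forced on all FASTA records.
#' @return A list of [sequence_record()] objects.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "tsv"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    recs <- lapply(seq_along(set), function(i) {
      s <- as.character(set[[i]])
      ab <- if (is.null(alphabet)) infer_alphabet(toupper(s)) else alphabet
      sequence_record(names(set)[i], s, ab)
    })
    return(recs)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "alphabet")
  if (!all(need %in% names(tab)))
    stop("TSV must have columns 'name', 'sequence', 'alphabet'", call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    tryCatch(
      sequence_record(tab$name[i], tab$sequence[i], tab$alphabet[i]),
      error = function(e) stop(sprintf("line %d of '%s': %s", i + 1L, path,
                                       conditionMessage(e)), call. = FALSE))
  })
}

#' Write sequence records to FASTA or TSV
#'
#' Symmetric to [read_sequences()]: writing then reading yields equal
#' records (for FASTA, provided the alphabet is inferable or re-supplied).
#'
#' @param recs List of [sequence_record()] objects.
#' @param path Output path.
#' @param format `"auto"`, `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(recs, path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  stopifnot(all(vapply(recs, inherits, logical(1L), "sequence_record")))
  if (format == "fasta") {
    set <- Biostrings::BStringSet(vapply(recs, `[[`, character(1L), "seq"))
    names(set) <- vapply(recs, `[[`, character(1L), "name")
    Biostrings::writeXStringSet(set, path)
  } else {
    tab <- data.frame(name = vapply(recs, `[[`, character(1L), "name"),
                      sequence = vapply(recs, `[[`, character(1L), "seq"),
                      alphabet = vapply(recs, `[[`, character(1L), "alphabet"),
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
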