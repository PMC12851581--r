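#' @keywords internal
"_PACKAGE"

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a protein sequence object
#'
#' Residue numbering is 1-based throughout the package; peptide intervals are
#' inclusive on both ends (the field's "peptide 16-20" convention).
#'
#' @param identifier character scalar naming the protein.
#' @param residues a single string or character vector of one-letter
#'   amino-acid codes (canonical 20 only).
#' @return An object of class \code{protein_sequence}: a list with
#'   \code{identifier} and \code{residues} (character vector, one per position).
#' @export
protein_sequence <- function(identifier, residues) {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  if (length(residues) == 0L)
    stop("protein sequence must have length > 0")
  bad <- setdiff(unique(residues), AA1)
  if (length(bad) > 0L)
    stop("non-canonical amino-acid code(s): ", paste(bad, collapse = ", "))
  structure(list(identifier = as.character(identifier), residues = residues),
            class = "protein_sequence")
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence>", x$identifier, "-", length(x$residues),
      "residues\n")
  invisible(x)
}

#' Subsequence of a protein as a single string
#' @param protein a \code{protein_sequence}.
#' @param start,end 1-based inclusive residue indices.
#' @return character scalar.
#' @export
subseq <- function(protein, start, end) {
  stopifnot(inherits(protein, "protein_sequence"),
            start >= 1, end <= length(protein), start <= end)
  paste(protein$residues[start:end], collapse = "")
}

#' Maximum exchangeable backbone amides of a peptide
#'
#' Standard HDX convention: the N-terminal amide back-exchanges too fast to
#' retain label and proline has no backbone amide hydrogen, so the count is
#' \code{length - 1 - (prolines beyond the first residue)}.
#'
#' @param peptide_sequence character vector of peptide sequences (one-letter
#'   codes).
#' @return integer vector of exchangeable-amide counts (>= 0).
#' @examples
#' max_exchangeable("GASTV")  # 4
#' max_exchangeable("GPPST")  # 2
#' @export
max_exchangeable <- function(peptide_sequence) {
  vapply(as.character(peptide_sequence), function(s) {
    if (nchar(s) == 0L) stop("empty peptide sequence")
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(unique(aa), AA1)
    if (length(bad) > 0L)
      stop("non-canonical amino-acid code(s) in peptide: ",
           paste(bad, collapse = ", "))
    length(aa) - 1L - sum(aa[-1L] == "P")
  }, integer(1), USE.NAMES = FALSE)
}

record_columns <- c("sequence", "start", "end", "state", "timepoint",
                    "replicate", "uptake")

validate_records <- function(records, protein, uptake_tol = 1e-6) {
  errs <- character(0)
  n <- nrow(records)
  if (n == 0L) return(errs)
  for (i in seq_len(n)) {
    r <- records[i, ]
    len <- r$end - r$start + 1L
    if (r$start > r$end)
      errs <- c(errs, sprintf("row %d: start %d > end %d", i, r$start, r$end))
    else if (len != nchar(r$sequence))
      errs <- c(errs, sprintf(
        "row %d: interval [%d,%d] width %d != sequence length %d (%s)",
        i, r$start, r$end, len, nchar(r$sequence), r$sequence))
    else if (r$end > length(protein) || r$start < 1L)
      errs <- c(errs, sprintf("row %d: interval [%d,%d] outside protein 1..%d",
                              i, r$start, r$end, length(protein)))
    else if (subseq(protein, r$start, r$end) != toupper(r$sequence))
      errs <- c(errs, sprintf(
        "row %d: peptide %s does not match protein at [%d,%d] (%s)",
        i, r$sequence, r$start, r$end, subseq(protein, r$start, r$end)))
    else {
      nex <- max_exchangeable(r$sequence)
      if (!is.na(r$uptake) && r$uptake > nex + uptake_tol)
        errs <- c(errs, sprintf(
          "row %d: uptake %.4g exceeds max exchangeable amides %d of %s",
          i, r$uptake, nex, r$sequence))
      if (!is.na(r$uptake) && r$uptake < 0)
        errs <- c(errs, sprintf("row %d: negative uptake %.4g", i, r$uptake))
    }
    if (!is.na(r$timepoint) && r$timepoint < 0)
      errs <- c(errs, sprintf("row %d: negative timepoint", i))
  }
  errs
}

#' Construct and validate an HDX-MS uptake dataset
#'
#' @param protein a \code{protein_sequence} the peptides refer to.
#' @param records data frame with columns \code{sequence}, \code{start},
#'   \code{end}, \code{state}, \code{timepoint} (seconds), \code{replicate},
#'   \code{uptake} (deuterons).
#' @param validate validate every record against the protein (default TRUE).
#' @return An \code{hdx_dataset}: list with \code{protein}, \code{records},
#'   plus derived \code{states} and \code{timepoints}.
#' @export
hdx_dataset <- function(protein, records, validate = TRUE) {
  stopifnot(inherits(protein, "protein_sequence"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[record_columns]
  records$sequence <- toupper(as.character(records$sequence))
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$state <- as.character(records$state)
  records$timepoint <- as.numeric(records$timepoint)
  records$replicate <- as.integer(records$replicate)
  records$uptake <- as.numeric(records$uptake)
  if (validate) {
    errs <- validate_records(records, protein)
    if (length(errs) > 0L)
      stop("invalid uptake records:\n  ", paste(errs, collapse = "\n  "))
  }
  key <- with(records, paste(sequence, start, end, state, timepoint, replicate))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (peptide, state, timepoint, replicate) row(s); keeping first")
    records <- records[!duplicated(key), , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(protein = protein, records = records,
                 states = sort(unique(records$state)),
                 timepoints = sort(unique(records$timepoint))),
            class = "hdx_dataset")
}

#' @export
print.hdx_dataset <- function(x, ...) {
  cat("<hdx_dataset>", x$protein$identifier, "-", nrow(x$records),
      "records;", length(unique(paste(x$records$start, x$records$end))),
      "peptides;", "states:", paste(x$states, collapse = ", "),
      "; timepoints (s):", paste(x$timepoints, collapse = ", "), "\n")
  invisible(x)
}

#' Read a peptide-level uptake table
#'
#' Ingests one-measurement-per-row delimited text (comma or tab autodetected)
#' as exported by HDX processing software. A column mapping translates
#' arbitrary vendor headers to the canonical fields.
#'
#' @param source path to a delimited text file (or a connection).
#' @param protein a \code{protein_sequence} for validation.
#' @param mapping named character vector mapping canonical field names
#'   (\code{sequence}, \code{start}, \code{end}, \code{state},
#'   \code{timepoint}, \code{replicate}, \code{uptake}) to the source's column
#'   headers; defaults to identity.
#' @param sep field separator; \code{NULL} (default) autodetects comma vs tab
#'   from the header line.
#' @param uptake_scale multiplicative correction applied to the uptake
#'   column on read (e.g. a back-exchange factor); default 1.
#' @return an \code{hdx_dataset}.
#' @export
read_uptake_table <- function(source, protein, mapping = NULL, sep = NULL,
                              uptake_scale = 1) {
  if (is.null(sep)) {
    header <- readLines(source, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(source, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (is.null(mapping))
    mapping <- stats::setNames(record_columns, record_columns)
  missing_fields <- setdiff(record_columns, names(mapping))
  if (length(missing_fields) > 0L)
    stop("column mapping lacks field(s): ",
         paste(missing_fields, collapse = ", "))
  absent <- setdiff(unname(mapping[record_columns]), names(tab))
  if (length(absent) > 0L)
    stop("input table lacks required column(s): ",
         paste(absent, collapse = ", "))
  records <- stats::setNames(tab[unname(mapping[record_columns])],
                             record_columns)
  records$uptake <- as.numeric(records$uptake) * uptake_scale
  hdx_dataset(protein, records)
}

#' Write an HDX dataset as canonical CSV
#'
#' Fixed column order, UTF-8; \code{read_uptake_table} on the output
#' reconstructs an equal dataset (round-trip property).
#'
#' @param ds an \code{hdx_dataset}.
#' @param sink output file path (or connection).
#' @export
write_dataset <- function(ds, sink) {
  stopifnot(inherits(ds, "hdx_dataset"))
  utils::write.csv(ds$records[record_columns], sink, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Peptide coverage statistics over a residue range
#'
#' A residue is covered if at least one peptide in the dataset spans it.
#' The percentage denominator is configurable because vendor software differs:
#' the analyzed range width (default) or the full protein length.
#'
#' @param ds an \code{hdx_dataset}.
#' @param residue_range inclusive \code{c(first, last)}; default full protein.
#' @param denominator \code{"range"} (default) or \code{"protein"}.
#' @return list with \code{covered} (count), \code{percent},
#'   \code{non_covered} (sorted positions), \code{n_peptides}.
#' @export
coverage_stats <- function(ds, residue_range = c(1L, length(ds$protein)),
                           denominator = c("range", "protein")) {
  stopifnot(inherits(ds, "hdx_dataset"))
  denominator <- match.arg(denominator)
  first <- as.integer(residue_range[1]); last <- as.integer(residue_range[2])
  stopifnot(first >= 1, last <= length(ds$protein), first <= last)
  peps <- unique(ds$records[c("start", "end")])
  hit <- rep(FALSE, last - first + 1L)
  for (i in seq_len(nrow(peps))) {
    a <- max(peps$start[i], first); b <- min(peps$end[i], last)
    if (a <= b) hit[(a:b) - first + 1L] <- TRUE
  }
  denom <- if (denominator == "range") last - first + 1L else length(ds$protein)
  list(covered = sum(hit),
       percent = 100 * sum(hit) / denom,
       non_covered = (first:last)[!hit],
       n_peptides = nrow(peps))
}
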