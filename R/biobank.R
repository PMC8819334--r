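# Candidate-biomarker bank assembly: merge accession lists from tissue
# differential analysis, serum differential analysis and literature, with
# provenance tracking, then restrict to serum-detectable candidates.

#' Normalize protein accessions
#'
#' Uppercases and strips isoform suffixes ("-1", "-2", ...) so the same
#' protein reported by mixed sources merges to one entry.
#'
#' @param accessions character vector.
#' @return normalized accessions.
#' @export
normalize_accession <- function(accessions) {
  sub("-[0-9]+$", "", toupper(trimws(accessions)))
}

#' Merge candidate lists into a biomarker bank
#'
#' Takes named accession lists (names become provenance tags, e.g.
#' `tissue_DEP`, `serum_DEP`, `literature`) and returns their union with
#' merged provenance, plus an overlap report (per-pair intersection
#' counts and the inclusion-exclusion check of the union size).
#'
#' @param lists named list; each element a character vector of accessions
#'   or a data.frame with an `accession` column and optional `symbol` /
#'   `serum_detectable` / `direction` columns.
#' @return list with `bank` (data.frame: accession, symbol, provenance,
#'   serum_detectable, direction) and `overlap` (list: pairwise counts,
#'   union size, total overlap correction).
#' @export
merge_bank <- function(lists) {
  if (!length(lists) || is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop("need a nonempty named list of candidate lists", call. = FALSE)
  }
  std <- lapply(names(lists), function(nm) {
    x <- lists[[nm]]
    if (is.character(x)) x <- data.frame(accession = x, stringsAsFactors = FALSE)
    stopifnot("accession" %in% names(x))
    x$accession <- normalize_accession(x$accession)
    x <- x[!duplicated(x$accession), , drop = FALSE]
    for (col in c("symbol", "direction")) {
      if (is.null(x[[col]])) x[[col]] <- NA_character_
    }
    if (is.null(x$serum_detectable)) x$serum_detectable <- NA
    x$provenance <- nm
    x[, c("accession", "symbol", "provenance", "serum_detectable",
          "direction")]
  })
  all_rows <- do.call(rbind, std)
  accs <- sort(unique(all_rows$accession))
  bank <- data.frame(accession = accs, stringsAsFactors = FALSE)
  by_acc <- split(all_rows, all_rows$accession)[accs]
  bank$symbol <- vapply(by_acc, function(d) {
    s <- d$symbol[!is.na(d$symbol)]
    if (length(s)) s[1L] else NA_character_
  }, character(1))
  bank$provenance <- vapply(by_acc, function(d) {
    paste(sort(unique(d$provenance)), collapse = ";")
  }, character(1))
  bank$serum_detectable <- vapply(by_acc, function(d) {
    s <- d$serum_detectable[!is.na(d$serum_detectable)]
    if (length(s)) any(as.logical(s)) else NA
  }, logical(1))
  bank$direction <- vapply(by_acc, function(d) {
    s <- d$direction[!is.na(d$direction)]
    if (length(s)) s[1L] else NA_character_
  }, character(1))
  rownames(bank) <- NULL

  sets <- lapply(std, function(d) d$accession)
  names(sets) <- names(lists)
  pairs <- if (length(sets) > 1L) utils::combn(names(sets), 2L, simplify = FALSE)
           else list()
  pairwise <- stats::setNames(
    vapply(pairs, function(pr) length(intersect(sets[[pr[1]]], sets[[pr[2]]])),
           integer(1)),
    vapply(pairs, paste, character(1), collapse = " & "))
  overlap_total <- sum(lengths(sets)) - length(accs)
  list(bank = bank,
       overlap = list(sizes = lengths(sets), pairwise = pairwise,
                      union = length(accs), total_overlap = overlap_total))
}

#' Restrict a bank to serum-detectable candidates
#'
#' An entry is kept when it has direct serum evidence (`serum_DEP` in its
#' provenance) or its serum-detectability flag — supplied upstream from
#' secretion/cellular-component annotation — is TRUE.
#'
#' @param bank data.frame from [merge_bank()].
#' @param serum_tag provenance tag counting as direct serum evidence.
#' @return the filtered bank (idempotent).
#' @export
filter_serum_detectable <- function(bank, serum_tag = "serum_DEP") {
  has_serum <- vapply(strsplit(bank$provenance, ";", fixed = TRUE),
                      function(p) serum_tag %in% p, logical(1))
  need_flag <- !has_serum
  if (any(need_flag & is.na(bank$serum_detectable))) {
    stop("serum_detectable flag missing for: ",
         paste(bank$accession[need_flag & is.na(bank$serum_detectable)],
               collapse = ", "), call. = FALSE)
  }
  out <- bank[has_serum | (!is.na(bank$serum_detectable) & bank$serum_detectable), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a bank TSV
#'
#' @param path TSV with columns accession, symbol, provenance
#'   (semicolon-joined), serum_detectable, direction.
#' @return data.frame.
#' @export
read_bank <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname read_bank
#' @param bank bank data.frame.
#' @export
write_bank <- function(bank, path) {
  utils::write.table(bank, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
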