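#' Marker catalogs
#'
#' A marker catalog is a data frame (class `marker_catalog`) with one row per
#' biallelic (or multi-copy / deletion) Y-chromosome marker:
#'
#' * `name` -- unique marker identifier (e.g. `"V249"`, `"M112"`, `"V161.1"`).
#'   A `".k"` suffix denotes one mutation event at a recurrent base site.
#' * `positions` -- list column of 1-based GRCh37 chrY coordinates, sorted
#'   and strictly positive.  Length > 1 only for multi-copy markers.  Stored
#'   exactly as printed, no liftover.
#' * `end` -- for deletions, the inclusive end of the deleted range
#'   (`NA` otherwise); the span `end - positions + 1` must equal the length
#'   of the deleted sequence.
#' * `ancestral`, `derived` -- alleles.  Substitutions carry two distinct
#'   single nucleotides; deletions carry the deleted sequence and `"-"`;
#'   multi-copy markers carry `"/"`-separated per-copy alleles, one per
#'   position.
#' * `class` -- one of `"substitution"`, `"deletion"`,
#'   `"multi_copy_substitution"`.
#' * `source_tag` -- provenance label (`"new-Table1"`, `"prior-146"`,
#'   `"backbone-59"`, ...).
#'
#' A deletion is modeled as one binary presence/absence character and a
#' multi-copy marker as one character whose paralogous positions are
#' metadata: both are genotyped as single phylogenetic events.
#'
#' @name marker_catalog
NULL

MUTATION_CLASSES <- c("substitution", "deletion", "multi_copy_substitution")

#' Construct a marker catalog
#'
#' @param name character vector of unique marker names.
#' @param positions list of integer vectors (one per marker) or an integer
#'   vector for single-position markers.
#' @param end integer vector of deletion range ends (`NA` for non-deletions).
#' @param ancestral,derived character vectors of alleles.
#' @param class character vector of mutation classes.
#' @param source_tag character vector of provenance labels.
#' @return A `marker_catalog` data frame.
#' @export
marker_catalog <- function(name, positions, end = NA_integer_, ancestral,
                           derived, class, source_tag = "unspecified") {
  if (!is.list(positions)) positions <- as.list(positions)
  positions <- lapply(positions, function(p) {
    p <- as.integer(p)
    if (all(is.na(p))) p else sort(p)
  })
  cat <- data.frame(name = as.character(name), stringsAsFactors = FALSE)
  cat$positions <- positions
  cat$end <- rep_len(as.integer(end), nrow(cat))
  cat$ancestral <- rep_len(as.character(ancestral), nrow(cat))
  cat$derived <- rep_len(as.character(derived), nrow(cat))
  cat$class <- rep_len(as.character(class), nrow(cat))
  cat$source_tag <- rep_len(as.character(source_tag), nrow(cat))
  class(cat) <- c("marker_catalog", "data.frame")
  validate_marker_catalog(cat)
  cat
}

#' Validate a marker catalog
#'
#' Checks the invariants documented in [marker_catalog]: unique names,
#' positive sorted coordinates, allele/class consistency, deletion span
#' equal to deleted-sequence length, and per-copy alleles for every
#' paralogous position of a multi-copy marker.
#'
#' @param cat a `marker_catalog`.
#' @return `cat`, invisibly; stops on the first violated invariant.
#' @export
validate_marker_catalog <- function(cat) {
  dup <- cat$name[duplicated(cat$name)]
  if (length(dup) > 0L)
    stop("duplicate marker name(s) in catalog: ", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(cat))) {
    nm <- cat$name[i]
    pos <- cat$positions[[i]]
    cls <- cat$class[i]
    if (!cls %in% MUTATION_CLASSES)
      stop("marker ", nm, ": unknown mutation class '", cls, "'")
    if (length(pos) >= 1L && !all(is.na(pos))) {
      if (any(pos <= 0L)) stop("marker ", nm, ": non-positive coordinate")
      if (is.unsorted(pos, strictly = TRUE) && length(pos) > 1L)
        stop("marker ", nm, ": positions must be strictly increasing")
    }
    if (length(pos) > 1L && cls != "multi_copy_substitution")
      stop("marker ", nm, ": multiple positions on a non-multi-copy marker")
    anc <- cat$ancestral[i]; der <- cat$derived[i]
    if (is.na(anc) || is.na(der)) next  # alleles optional for list-only markers
    if (cls == "substitution") {
      if (!grepl("^[ACGT]$", anc) || !grepl("^[ACGT]$", der) || anc == der)
        stop("marker ", nm, ": substitution needs two distinct single nucleotides")
    } else if (cls == "deletion") {
      if (der != "-")
        stop("marker ", nm, ": deletion derived allele must be '-'")
      if (is.na(cat$end[i]))
        stop("marker ", nm, ": deletion without range end")
      span <- cat$end[i] - pos[1] + 1L
      if (span != nchar(anc))
        stop("marker ", nm, ": deletion span ", span,
             " != deleted-sequence length ", nchar(anc))
    } else {  # multi-copy
      anc_c <- strsplit(anc, "/", fixed = TRUE)[[1]]
      der_c <- strsplit(der, "/", fixed = TRUE)[[1]]
      if (length(anc_c) != length(pos) || length(der_c) != length(pos))
        stop("marker ", nm, ": per-copy alleles must be listed for every position")
    }
  }
  invisible(cat)
}

parse_position_field <- function(txt, row_label) {
  txt <- gsub("[[:space:]]+", "", txt)
  if (txt == "" || toupper(txt) == "NA")
    return(list(positions = NA_integer_, end = NA_integer_))
  if (grepl("-", txt, fixed = TRUE)) {
    parts <- strsplit(txt, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))))
      stop("row ", row_label, ": malformed position range '", txt, "'")
    return(list(positions = as.integer(parts[1]), end = as.integer(parts[2])))
  }
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  pos <- suppressWarnings(as.integer(parts))
  if (anyNA(pos))
    stop("row ", row_label, ": malformed position field '", txt, "'")
  list(positions = pos, end = NA_integer_)
}

parse_mutation_field <- function(txt, row_label) {
  txt <- trimws(txt)
  if (grepl("^del[[:space:]]*", txt)) {
    seq <- toupper(sub("^del[[:space:]]*", "", txt))
    if (!grepl("^[ACGT]+$", seq))
      stop("row ", row_label, ": malformed deletion '", txt, "'")
    return(list(ancestral = seq, derived = "-", class = "deletion"))
  }
  # "X to Y" with tolerant whitespace ("T/T/T toG/G/G")
  parts <- strsplit(txt, "[[:space:]]*to[[:space:]]*")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) != 2L)
    stop("row ", row_label, ": malformed mutation field '", txt, "'")
  anc <- toupper(gsub("[[:space:]]", "", parts[1]))
  der <- toupper(gsub("[[:space:]]", "", parts[2]))
  multi <- grepl("/", anc, fixed = TRUE) || grepl("/", der, fixed = TRUE)
  ok <- function(a) grepl("^[ACGT](/[ACGT])*$", a)
  if (!ok(anc) || !ok(der))
    stop("row ", row_label, ": malformed mutation field '", txt, "'")
  list(ancestral = anc, derived = der,
       class = if (multi) "multi_copy_substitution" else "substitution")
}

#' Parse a marker table
#'
#' Reads a tab-separated marker table in either of two dialects:
#'
#' * the *lenient* dialect of published marker tables, with columns
#'   `SNP`, `Y-Position`, `Mutation` (and optional primer columns).
#'   Position fields may hold semicolon-separated coordinates (whitespace
#'   irregular, e.g. a coordinate glued after a semicolon) or a
#'   `"start - end"` range; mutation fields match `"X to Y"`,
#'   `"X/X/X to Y/Y/Y"` (the space before the second allele may be
#'   missing) or `"del SEQ"`.
#' * the *canonical* dialect written by [write_marker_table()], with
#'   columns `name`, `positions`, `end`, `ancestral`, `derived`, `class`,
#'   `source_tag`.
#'
#' The dialect is auto-detected from the header row.
#'
#' @param file path to a TSV file, or a character vector of lines.
#' @param source_tag provenance label applied to all rows of a lenient-dialect
#'   table (canonical tables carry their own).
#' @return A [marker_catalog].
#' @export
parse_marker_table <- function(file, source_tag = "new-Table1") {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty marker table (no header row)")
  header <- tolower(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  canonical <- all(c("name", "positions", "ancestral", "derived", "class") %in% header)
  rows <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  if (length(rows) == 0L)
    return(marker_catalog(character(0), list(), integer(0), character(0),
                          character(0), character(0), character(0)))
  if (canonical) {
    idx <- function(col) match(col, header)
    get <- function(r, col) if (!is.na(idx(col)) && length(r) >= idx(col)) r[[idx(col)]] else NA_character_
    name <- vapply(rows, get, "", "name")
    posl <- lapply(seq_along(rows), function(i) {
      pf <- parse_position_field(get(rows[[i]], "positions"), name[i])
      pf$positions
    })
    endv <- vapply(seq_along(rows), function(i) {
      e <- get(rows[[i]], "end")
      if (is.na(e) || e == "" || toupper(e) == "NA") NA_integer_ else as.integer(e)
    }, integer(1))
    na_if_empty <- function(x) ifelse(is.na(x) | x == "" | toupper(x) == "NA", NA_character_, x)
    marker_catalog(name, posl, endv,
                   na_if_empty(vapply(rows, get, "", "ancestral")),
                   na_if_empty(vapply(rows, get, "", "derived")),
                   vapply(rows, get, "", "class"),
                   vapply(rows, get, "", "source_tag"))
  } else {
    # lenient dialect: name, position, mutation, [primers...]
    name <- vapply(rows, function(r) trimws(r[[1]]), "")
    parsed_pos <- lapply(seq_along(rows), function(i) {
      if (length(rows[[i]]) < 2L) stop("row ", name[i], ": missing position field")
      parse_position_field(rows[[i]][[2]], name[i])
    })
    parsed_mut <- lapply(seq_along(rows), function(i) {
      if (length(rows[[i]]) < 3L) stop("row ", name[i], ": missing mutation field")
      parse_mutation_field(rows[[i]][[3]], name[i])
    })
    cat <- marker_catalog(
      name,
      lapply(parsed_pos, `[[`, "positions"),
      vapply(parsed_pos, `[[`, integer(1), "end"),
      vapply(parsed_mut, `[[`, "", "ancestral"),
      vapply(parsed_mut, `[[`, "", "derived"),
      vapply(parsed_mut, `[[`, "", "class"),
      source_tag)
    cat
  }
}

#' Write a marker catalog in the canonical dialect
#'
#' The canonical dialect round-trips: `parse_marker_table(write_marker_table(x))`
#' is the identity on all fields.
#'
#' @param cat a [marker_catalog].
#' @param file path, or `NULL` to return the lines invisibly.
#' @return The lines written, invisibly.
#' @export
write_marker_table <- function(cat, file = NULL) {
  pos_txt <- vapply(seq_len(nrow(cat)), function(i) {
    p <- cat$positions[[i]]
    if (length(p) == 1L && is.na(p)) "NA" else paste(p, collapse = ";")
  }, "")
  fmt <- function(x) ifelse(is.na(x), "NA", as.character(x))
  lines <- c(
    paste(c("name", "positions", "end", "ancestral", "derived", "class",
            "source_tag"), collapse = "\t"),
    vapply(seq_len(nrow(cat)), function(i) {
      paste(c(cat$name[i], pos_txt[i], fmt(cat$end[i]), fmt(cat$ancestral[i]),
              fmt(cat$derived[i]), cat$class[i], cat$source_tag[i]),
            collapse = "\t")
    }, ""))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Select markers by V-name numeric range
#'
#' Returns the sub-catalog of markers whose name matches the `V<number>`
#' pattern with numeric suffix in `[lo, hi]`.  Event suffixes (`V161.1`)
#' are ignored when extracting the number; non-V-style names are skipped,
#' not errors.
#'
#' @param cat a [marker_catalog].
#' @param lo,hi inclusive bounds on the numeric suffix (`lo <= hi`).
#' @return A `marker_catalog` subset.
#' @export
select_by_name_range <- function(cat, lo, hi) {
  stopifnot(lo <= hi)
  m <- regmatches(cat$name, regexec("^V([0-9]+)(\\.[0-9]+)?$", cat$name))
  num <- vapply(m, function(x) if (length(x) >= 2L) as.numeric(x[2]) else NA_real_,
                numeric(1))
  keep <- !is.na(num) & num >= lo & num <= hi
  out <- cat[keep, , drop = FALSE]
  class(out) <- c("marker_catalog", "data.frame")
  out
}

#' Read an outgroup allele table
#'
#' Two-column TSV (`site`, `allele`): the nucleotide observed at each base
#' site in the outgroup (chimpanzee) reference, used to polarize mutation
#' events.  One record per site; alleles are single nucleotides.
#'
#' @param file path or character vector of lines.
#' @return A data frame with columns `site` and `allele`.
#' @export
read_outgroup_table <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- tolower(trimws(rows[[1]]))
  if (identical(hdr[1:2], c("site", "allele"))) rows <- rows[-1]
  site <- vapply(rows, function(r) trimws(r[[1]]), "")
  allele <- toupper(vapply(rows, function(r) trimws(r[[2]]), ""))
  if (anyDuplicated(site)) stop("duplicate site in outgroup table")
  bad <- !grepl("^[ACGT]$", allele)
  if (any(bad))
    stop("outgroup allele must be a single nucleotide: ", site[bad][1])
  data.frame(site = site, allele = allele, stringsAsFactors = FALSE)
}

#' Write an outgroup allele table
#' @param tab data frame with columns `site`, `allele`.
#' @param file path, or `NULL` to return lines.
#' @return Lines written, invisibly.
#' @export
write_outgroup_table <- function(tab, file = NULL) {
  lines <- c("site\tallele", paste(tab$site, tab$allele, sep = "\t"))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
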