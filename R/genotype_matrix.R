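#' Genotype matrices
#'
#' A `genotype_matrix` holds three-valued state calls for a panel of Y
#' chromosomes at a set of markers:
#'
#' * `samples` -- data frame of sample records (`sample_id`, unique;
#'   `prior_haplogroup`, the backbone haplogroup each sample was assigned
#'   to before mapping, or `NA`; `origin`, free text).
#' * `markers` -- character vector of marker names (catalog order).
#' * `state` -- character matrix (samples x markers) over
#'   `"D"` (derived), `"A"` (ancestral), `"N"` (no call).
#' * `raw_allele` -- optional character matrix of raw nucleotides, needed
#'   for triallelic sites; `NA` where not recorded.
#'
#' A no-call never counts as derived anywhere; operations that need to
#' ignore untested samples expose an explicit observed-only policy.
#'
#' @name genotype_matrix
NULL

GT_STATES <- c("D", "A", "N")

#' Construct a genotype matrix
#'
#' @param state character matrix with rownames = sample ids and colnames =
#'   marker names, entries in `"D"`, `"A"`, `"N"`.
#' @param samples optional data frame with columns `sample_id`,
#'   `prior_haplogroup`, `origin`; defaults to bare records from rownames.
#' @param raw_allele optional character matrix, same dimnames as `state`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(state, samples = NULL, raw_allele = NULL) {
  state <- as.matrix(state)
  if (is.null(rownames(state)) || is.null(colnames(state)))
    stop("state matrix needs sample rownames and marker colnames")
  if (!all(state %in% GT_STATES))
    stop("states must be one of D, A, N")
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(state),
                          prior_haplogroup = NA_character_,
                          origin = NA_character_, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (!identical(sort(samples$sample_id), sort(rownames(state))))
    stop("sample records do not match state matrix rows")
  samples <- samples[match(rownames(state), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(raw_allele)) {
    raw_allele <- as.matrix(raw_allele)
    if (!identical(dimnames(raw_allele), dimnames(state)))
      stop("raw_allele dimnames must match state dimnames")
  }
  structure(list(samples = samples, markers = colnames(state),
                 state = state, raw_allele = raw_allele),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$state), "samples x", ncol(x$state), "markers\n")
  tab <- table(factor(x$state, levels = GT_STATES))
  cat(sprintf("  calls: D=%d A=%d N=%d\n", tab[["D"]], tab[["A"]], tab[["N"]]))
  invisible(x)
}

#' Derived-sample set of a marker
#'
#' @param gm a [genotype_matrix].
#' @param marker marker name present in `gm`.
#' @return A list with `marker`, `members` (sample ids with a derived call)
#'   and `observed` (sample ids with any call); `members` is always a
#'   subset of `observed`.
#' @export
derived_set <- function(gm, marker) {
  j <- match(marker, gm$markers)
  if (is.na(j)) stop("unknown marker: ", marker)
  col <- gm$state[, j]
  list(marker = marker,
       members = rownames(gm$state)[col == "D"],
       observed = rownames(gm$state)[col != "N"])
}

#' Count markers at which every sample of a subset is derived
#'
#' With the default policy a no-call counts as failure (the sample is not
#' known to be derived, so the marker is not shared-derived).  With
#' `policy = "observed-only"` untested samples are ignored and a marker
#' counts when every *observed* sample of the subset is derived (markers
#' with no observed sample in the subset never count).
#'
#' @param gm a [genotype_matrix].
#' @param sample_subset non-empty character vector of sample ids.
#' @param marker_subset non-empty character vector of marker names.
#' @param policy `"strict"` (default) or `"observed-only"`.
#' @return Integer count.
#' @export
shared_derived_count <- function(gm, sample_subset, marker_subset,
                                 policy = c("strict", "observed-only")) {
  policy <- match.arg(policy)
  if (length(sample_subset) == 0L || length(marker_subset) == 0L)
    stop("sample and marker subsets must be non-empty")
  mk <- intersect(marker_subset, gm$markers)
  if (length(mk) == 0L) stop("no marker of the subset is present in the matrix")
  miss <- setdiff(sample_subset, rownames(gm$state))
  if (length(miss) > 0L) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  sub <- gm$state[sample_subset, mk, drop = FALSE]
  if (policy == "strict") {
    sum(apply(sub, 2L, function(col) all(col == "D")))
  } else {
    sum(apply(sub, 2L, function(col) {
      obs <- col != "N"
      any(obs) && all(col[obs] == "D")
    }))
  }
}

#' Read a genotype matrix from TSV
#'
#' Sample-major TSV: first column `sample_id`, optional `prior_haplogroup`
#' and `origin` columns, then one column per marker holding `D`/`A`/`N`.
#' An optional companion TSV of identical layout carries raw alleles.
#'
#' @param file path to the state TSV (or character vector of lines).
#' @param raw_file optional path to the raw-allele TSV.
#' @return A [genotype_matrix].
#' @export
read_genotype_matrix <- function(file, raw_file = NULL) {
  read_tab <- function(f) {
    lines <- if (length(f) == 1L && file.exists(f)) readLines(f) else f
    lines <- lines[nzchar(trimws(lines))]
    rows <- strsplit(lines, "\t", fixed = TRUE)
    hdr <- rows[[1]]
    body <- rows[-1]
    m <- do.call(rbind, lapply(body, function(r) {
      length(r) <- length(hdr)
      r
    }))
    colnames(m) <- hdr
    m
  }
  m <- read_tab(file)
  meta_cols <- intersect(c("sample_id", "prior_haplogroup", "origin"), colnames(m))
  marker_cols <- setdiff(colnames(m), meta_cols)
  state <- m[, marker_cols, drop = FALSE]
  rownames(state) <- m[, "sample_id"]
  state[is.na(state) | state == ""] <- "N"
  samples <- data.frame(
    sample_id = m[, "sample_id"],
    prior_haplogroup = if ("prior_haplogroup" %in% meta_cols) {
      v <- m[, "prior_haplogroup"]; ifelse(v == "NA" | v == "", NA_character_, v)
    } else NA_character_,
    origin = if ("origin" %in% meta_cols) {
      v <- m[, "origin"]; ifelse(v == "NA" | v == "", NA_character_, v)
    } else NA_character_,
    stringsAsFactors = FALSE)
  raw <- NULL
  if (!is.null(raw_file)) {
    rm_ <- read_tab(raw_file)
    raw_markers <- setdiff(colnames(rm_), meta_cols)
    raw <- matrix(NA_character_, nrow(state), ncol(state), dimnames = dimnames(state))
    rr <- rm_[, raw_markers, drop = FALSE]
    rownames(rr) <- rm_[, "sample_id"]
    rr[rr == "NA" | rr == ""] <- NA_character_
    raw[rownames(rr), raw_markers] <- rr
  }
  genotype_matrix(state, samples, raw)
}

#' Write a genotype matrix to TSV
#'
#' @param gm a [genotype_matrix].
#' @param file path for the state TSV, or `NULL` to return lines.
#' @param raw_file optional path for the raw-allele companion TSV.
#' @return The state-table lines, invisibly.
#' @export
write_genotype_matrix <- function(gm, file = NULL, raw_file = NULL) {
  fmt <- function(x) ifelse(is.na(x), "NA", x)
  hdr <- paste(c("sample_id", "prior_haplogroup", "origin", gm$markers),
               collapse = "\t")
  lines <- c(hdr, vapply(seq_len(nrow(gm$state)), function(i) {
    paste(c(gm$samples$sample_id[i], fmt(gm$samples$prior_haplogroup[i]),
            fmt(gm$samples$origin[i]), gm$state[i, ]), collapse = "\t")
  }, ""))
  if (!is.null(file)) writeLines(lines, file)
  if (!is.null(raw_file) && !is.null(gm$raw_allele)) {
    rl <- c(hdr, vapply(seq_len(nrow(gm$state)), function(i) {
      paste(c(gm$samples$sample_id[i], fmt(gm$samples$prior_haplogroup[i]),
              fmt(gm$samples$origin[i]), fmt(gm$raw_allele[i, ])),
            collapse = "\t")
    }, ""))
    writeLines(rl, raw_file)
  }
  invisible(lines)
}
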