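#' Packaged study fixture
#'
#' Builds, entirely in code, the fixture encoding the basal portion of the
#' human MSY haplogroup tree and the 51-chromosome genotyping panel used
#' throughout the package's worked examples:
#'
#' * the *backbone*: the previously published haplogroup topology
#'   (Karafet-style clades under the revised basal root) carrying 59
#'   backbone markers on their published branches and 146 previously
#'   reported markers at their coarse, pre-refinement positions (markers
#'   discovered by sequencing single chromosomes are lumped on the
#'   lineage branch of the sequenced chromosome);
#' * the *catalog* of 227 markers: the 22 newly described mutations
#'   (parsed from the packaged marker table), the 146 previously reported
#'   mutations and the 59 backbone markers.  Branch-by-branch identities
#'   of the previously reported markers are not published as a list, so
#'   all fixture names for them except the paper-named ones (V20, V45,
#'   V69, V88, V104, V161, V186, V205, V218, V231, PK1) are synthetic
#'   V-numbers -- see the fixture manifest returned in `$manifest`;
#' * the *genotype matrix*: 51 samples x 227 markers with three-valued
#'   calls, typed per clade panel (untyped combinations are no-calls) and
#'   raw alleles at the triallelic V161 site;
#' * the *outgroup* allele table (chimpanzee reference) for the newly
#'   described sites and V161;
#' * the *figure tree*: the refined topology the panel encodes, against
#'   which the pipeline's output can be compared.
#'
#' The two collapsed substructures below B2b (drawn as triangles with 2
#' and 8 internal branches) are encoded as collapsed nodes and excluded
#' from new-haplogroup counting.
#'
#' @return List with `backbone`, `catalog`, `gm`, `outgroup`,
#'   `figure_tree`, `panels` (marker/sample sets per clade panel) and
#'   `manifest` (data frame mapping each marker to its fixture status).
#' @export
build_paper_fixture <- function() {
  ## ---- marker name blocks --------------------------------------------------
  a1b_stem <- c("V148", "V149", "V150", "V152", "V153", "V154", "V157",
                "V158", "V159", "V160", "V162", "V177", "V178", "V179",
                "V180", "V181", "V182", "V184", "V185")
  a1b_x2 <- c("V163", "V164", "V165", "V166", "V167")
  a1b_x3 <- c("V168", "V169", "V170", "V171", "V172")
  a1b_term <- c("V173", "V174", "V176")
  a1b32 <- c(a1b_stem, a1b_x2, a1b_x3, a1b_term)

  a1a_stem <- c("V189", "V190", "V191", "V192", "V193", "V194", "V195",
                "V196", "V197", "V198", "V199", "V200", "V201", "V202",
                "V203", "V204", "V206")
  a1a_split <- c("V207", "V208", "V209")
  a1a20 <- c(a1a_stem, a1a_split)

  a2_stem <- c("V211", "V212", "V213", "V214", "V215", "V216", "V217",
               "V219", "V220", "V222", "V223", "V224", "V226", "V228",
               "V232", "V234", "V236", "V238")
  a2_19 <- c(a2_stem, "V218")

  a3_stem <- c("V240", "V242", "V243", "V244", "V245", "V246")
  a3b_stem <- c("V247", "V250", "V251", "V252")
  a3a_stem <- c("V257", "V258")
  a3a1 <- c("V253", "V255")
  a3b1a_p <- c("V50", "V52")
  a3b1b_p <- c("V53", "V55")
  a3b2a_p <- c("V56", "V57")
  a3b2b_p <- c("V58", "V59")
  a3_22 <- c(a3_stem, a3b_stem, a3a_stem, a3a1, a3b1a_p, a3b1b_p,
             a3b2a_p, a3b2b_p)

  b_stem <- c("V60", "V61")
  b2_stem <- c("V62", "V63")
  b2a_stem <- "V64"
  b_n1 <- c("V65", "V66"); b_n2 <- c("V67", "V68"); b_n3 <- c("V70", "V71")
  b_n4 <- c("V72", "V74"); b_n5 <- c("V75", "V76")
  b_m109 <- c("V77", "V78")
  b_17 <- c(b_stem, b2_stem, b2a_stem, b_n1, b_n2, b_n3, b_n4, b_n5, b_m109)

  c_stem <- c("V21", "V22", "V23", "V24", "V25", "V26", "V27", "V28")
  c7 <- c("V20", "V29", "V30")
  c_11 <- c(c_stem, c7)

  ct_7 <- c("V9", "V10", "V12", "V13", "V14", "V15", "V16")
  r_7 <- c("V45", "V69", "V88", "V186", "V205", "V104", "V231")
  a1at_4 <- c("V221", "V225", "V227", "V229")
  a2t_3 <- c("V230", "V233", "V235")
  bt_3 <- c("V237", "V239", "V241")

  prior146 <- c(a1b32, a1a20, a2_19, a3_22, b_17, c_11, ct_7, r_7,
                a1at_4, a2t_3, bt_3, "V161")
  stopifnot(length(prior146) == 146L, !anyDuplicated(prior146))

  a3_new9 <- c("V262", "V265", "V303", "V304", "V305", "V306", "V313",
               "V314", "V317")

  ## ---- backbone tree: node, parent, markers at pre-study positions ---------
  bb <- list(
    list("A1b",        "Root",   c("P114", "V161", a1b32)),
    list("A1a-T",      "Root",   a1at_4),
    list("A1a",        "A1a-T",  c("M31", "P82", a1a20)),
    list("A2-T",       "A1a-T",  c("P108", a2t_3)),
    list("A2'3",       "A2-T",   "PK1"),
    list("A2",         "A2'3",   c("P3", "M14", a2_19)),
    list("A-M114",     "A2",     "M114"),
    list("A-P28",      "A2",     "P28"),
    list("A-P262",     "A2",     "P262"),
    list("A3",         "A2'3",   c("M32", a3_22)),
    list("A3a",        "A3",     c("M28", "M59")),
    list("A3b",        "A3",     c("M144", "M190", "P289")),
    list("A3b1",       "A3b",    "M51"),
    list("A3b2",       "A3b",    c("M13", "M118", "M171")),
    list("BT",         "A2-T",   c("M42", "M91", "M94", "P97", bt_3)),
    list("B",          "BT",     c("M60", "M181", "P85", "P90", b_17)),
    list("B1",         "B",      c("M236", "M288")),
    list("B2",         "B",      "M182"),
    list("B2a",        "B2",     "M150"),
    list("B-M109",     "B2a",    "M109"),
    list("B2b",        "B2",     c("M192", "M112")),
    list("B-M108.1",   "B2b",    "M108.1", 2L),
    list("B-50f2(P)",  "B2b",    "50f2(P)", 8L),
    list("B2c",        "B2",     "P6"),
    list("CT",         "BT",     c("M168", "M294", "P9.1", ct_7)),
    list("DE",         "CT",     c("YAP", "M145")),
    list("CF",         "CT",     "P143"),
    list("C",          "CF",     c("RPS4Y711", "M130", c_11)),
    list("C1",         "C",      "M8"),
    list("C2",         "C",      "M38"),
    list("C3",         "C",      "M217"),
    list("C4",         "C",      "M347"),
    list("C5",         "C",      "M356"),
    list("C6",         "C",      "P55"),
    list("F",          "CF",     c("M89", "M213")),
    list("K",          "F",      "M9"),
    list("P",          "K",      "M45"),
    list("R",          "P",      c("M207", "M173", "M306", r_7)))
  backbone59 <- c("P114", "M31", "P82", "P108", "PK1", "P3", "M14", "M114",
                  "P28", "P262", "M32", "M28", "M59", "M144", "M190", "P289",
                  "M51", "M13", "M118", "M171", "M42", "M91", "M94", "P97",
                  "M60", "M181", "P85", "P90", "M236", "M288", "M182",
                  "M150", "M109", "M192", "M112", "M108.1", "50f2(P)", "P6",
                  "M168", "M294", "P9.1", "YAP", "M145", "P143", "RPS4Y711",
                  "M130", "M8", "M38", "M217", "M347", "M356", "P55", "M89",
                  "M213", "M9", "M45", "M207", "M173", "M306")
  stopifnot(length(backbone59) == 59L, !anyDuplicated(backbone59))

  build_tree <- function(spec, marker_slot = 3L) {
    tree <- haplo_tree("Root")
    for (nd in spec) {
      par <- ht_node_by_name(tree, nd[[2]])
      stopifnot(!is.na(par))
      tree <- ht_add_node(tree, par, name = nd[[1]],
                          markers = unlist(nd[marker_slot]),
                          collapsed = if (length(nd) >= 4L) nd[[4]] else 0L)$tree
    }
    tree
  }
  backbone <- build_tree(bb)
  validate_haplo_tree(backbone)

  ## ---- figure tree: the refined topology the panel encodes -----------------
  fig <- list(
    list("A1b",        "Root",   c(a1b_stem, "V161.1")),
    list("A-V163",     "A1b",    a1b_x2),
    list("A-V168",     "A-V163", a1b_x3),
    list("A-P114",     "A-V168", c("P114", a1b_term)),
    list("A1a-T",      "Root",   c(a1at_4, "V2", "V3", "V11", "V33", "V34",
                                   "V37", "V161.2")),
    list("A1a",        "A1a-T",  c("M31", "P82", a1a_stem)),
    list("A-V147",     "A1a",    c("V147", a1a_split)),
    list("A2-T",       "A1a-T",  c("P108", a2t_3)),
    list("A2'3",       "A2-T",   c("PK1", "V249")),
    list("A2",         "A2'3",   c("P3", "M14", a2_stem)),
    list("A-M114",     "A2",     c("M114", "V73")),
    list("A-P28",      "A2",     "P28"),
    list("A-P262",     "A2",     "P262"),
    list("A-V218",     "A-P262", "V218"),
    list("A3",         "A2'3",   c("M32", "P289", a3_stem)),
    list("A3a",        "A3",     c("M28", "M59", a3a_stem)),
    list("A-V253",     "A3a",    a3a1),
    list("A3b",        "A3",     c("M144", "M190", a3b_stem)),
    list("A3b1",       "A3b",    "M51"),
    list("A-V262",     "A3b1",   c("V262", "V265", a3b1a_p)),
    list("A-V303",     "A3b1",   c("V303", "V304", a3b1b_p)),
    list("A3b2",       "A3b",    c("M13", "M118", "M171")),
    list("A-V305",     "A3b2",   c("V305", "V306", a3b2a_p)),
    list("A-V313",     "A3b2",   c("V313", "V314", "V317", a3b2b_p)),
    list("BT",         "A2-T",   c("M42", "M91", "M94", "P97", bt_3)),
    list("B",          "BT",     c("M60", "M181", "P85", "P90", b_stem)),
    list("B1",         "B",      c("M236", "M288")),
    list("B2",         "B",      c("M182", b2_stem, "V254")),
    list("B2a",        "B2",     c("M150", b2a_stem)),
    list("B-V65",      "B2a",    b_n1),
    list("B-V67",      "B-V65",  b_n2),
    list("B-V70",      "B-V67",  b_n3),
    list("B-V72",      "B-V70",  b_n4),
    list("B-V75",      "B-V72",  b_n5),
    list("B-M109",     "B-V75",  c("M109", b_m109, "V341")),
    list("B-M112",     "B2",     "M112"),
    list("B2b",        "B-M112", "M192"),
    list("B-M108.1",   "B2b",    "M108.1", 2L),
    list("B-50f2(P)",  "B2b",    "50f2(P)", 8L),
    list("B2c",        "B-M112", "P6"),
    list("CT",         "BT",     c("M168", "M294", "P9.1", ct_7)),
    list("DE",         "CT",     c("YAP", "M145")),
    list("CF",         "CT",     "P143"),
    list("C",          "CF",     c("RPS4Y711", "M130", c_stem)),
    list("C1",         "C",      "M8"),
    list("C2",         "C",      c("M38", "V248")),
    list("C3",         "C",      c("M217", "V87")),
    list("C4",         "C",      "M347"),
    list("C5",         "C",      "M356"),
    list("C6",         "C",      "P55"),
    list("C-V20",      "C",      c7),
    list("F",          "CF",     c("M89", "M213", "V186", "V205")),
    list("K",          "F",      c("M9", "V104")),
    list("P",          "K",      c("M45", "V231")),
    list("R",          "P",      c("M207", "M173", "M306", "V45", "V69",
                                   "V88")))
  figure_tree <- build_tree(fig)
  validate_haplo_tree(figure_tree)

  ## ---- samples -------------------------------------------------------------
  smp <- function(id, prior, fig_node, origin)
    data.frame(sample_id = id, prior_haplogroup = prior, fig_node = fig_node,
               origin = origin, stringsAsFactors = FALSE)
  samples <- rbind(
    smp("1",  "A1b",   "A1b",      "Algeria"),
    smp("2",  "A1b",   "A-V163",   "Cameroon"),
    smp("3",  "A1b",   "A-V168",   "Ghana"),
    smp("4",  "A1b",   "A-P114",   "Ghana"),
    smp("5",  "A1a",   "A-V147",   "Morocco"),
    smp("6",  "A1a",   "A1a",      "Mali"),
    smp("7",  "A-M114", "A-M114",  "South Africa"),
    smp("8",  "A-P262", "A-P262",  "South Africa"),
    smp("9",  "A-P262", "A-V218",  "Central African Republic"),
    smp("10", "A3a",   "A3a",      "Ethiopia"),
    smp("11", "A3a",   "A-V253",   "Ethiopia"),
    smp("12", "A3b1",  "A-V262",   "South Africa"),
    smp("13", "A3b1",  "A-V262",   "Namibia"),
    smp("14", "A3b1",  "A-V303",   "South Africa"),
    smp("15", "A3b1",  "A-V303",   "Botswana"),
    smp("16", "A3b2",  "A-V305",   "Ethiopia"),
    smp("17", "A3b2",  "A-V305",   "Kenya"),
    smp("18", "A3b2",  "A-V313",   "Sudan"),
    smp("19", "A3b2",  "A-V313",   "Ethiopia"),
    smp("20", "B1",    "B1",       "Mali"),
    smp("21", "B2a",   "B2a",      "Cameroon"),
    smp("22", "B2a",   "B-V65",    "Cameroon"),
    smp("23", "B2a",   "B-V67",    "Central African Republic"),
    smp("24", "B2a",   "B-V70",    "Gabon"),
    smp("25", "B2a",   "B-V72",    "Kenya"),
    smp("26", "B2a",   "B-V75",    "Uganda"),
    smp("27", "B-M109", "B-M109",  "Kenya"),
    smp("28", "B-M108.1", "B-M108.1", "Central African Republic"),
    smp("29", "B-50f2(P)", "B-50f2(P)", "D.R. Congo"),
    smp("30", "B2b",   "B2b",      "Central African Republic"),
    smp("31", "B2c",   "B2c",      "Cameroon"),
    smp("32", "B2c",   "B2c",      "Cameroon"),
    smp("33", "DE",    "DE",       "Nigeria"),
    smp("34", "C1",    "C1",       "Japan"),
    smp("35", "C2",    "C2",       "Indonesia"),
    smp("36", "C3",    "C3",       "Mongolia"),
    smp("37", "C4",    "C4",       "Australia"),
    smp("38", "C5",    "C5",       "India"),
    smp("39", "C",     "C-V20",    "Italy"),
    smp("40", "F",     "F",        "Nepal"),
    smp("41", "F",     "F",        "India"),
    smp("42", "F",     "F",        "Georgia"),
    smp("43", "F",     "F",        "Turkey"),
    smp("44", "K",     "K",        "Indonesia"),
    smp("45", "K",     "K",        "Australia"),
    smp("46", "K",     "K",        "India"),
    smp("47", "K",     "K",        "Pakistan"),
    smp("48", "P",     "P",        "Siberia"),
    smp("49", "P",     "P",        "Siberia"),
    smp("50", "R",     "R",        "Italy"),
    smp("51", "R",     "R",        "Ireland"))
  stopifnot(nrow(samples) == 51L)

  ## ---- typing scheme: which markers were assayed in which samples ----------
  all51 <- samples$sample_id
  typed <- list()
  for (m in c(backbone59, ct_7, bt_3, a1at_4, a2t_3, "V161",
              "V2", "V3", "V11", "V33", "V34", "V37"))
    typed[[m]] <- all51
  for (m in a1b32) typed[[m]] <- as.character(1:4)
  for (m in c(a1a20, "V147")) typed[[m]] <- as.character(5:6)
  for (m in c(a2_19, "V73")) typed[[m]] <- as.character(7:9)
  typed[["V249"]] <- as.character(7:19)
  for (m in c(a3_22, a3_new9)) typed[[m]] <- as.character(10:19)
  for (m in c(b_17, "V254", "V341")) typed[[m]] <- as.character(20:32)
  for (m in c(c_11, "V248", "V87")) typed[[m]] <- as.character(34:39)
  for (m in r_7) typed[[m]] <- as.character(33:51)

  ## ---- genotype matrix from the figure tree --------------------------------
  fig_attached <- figure_tree
  for (i in seq_len(nrow(samples))) {
    id <- ht_node_by_name(fig_attached, samples$fig_node[i])
    stopifnot(!is.na(id))
    fig_attached$samples[[id]] <- c(fig_attached$samples[[id]],
                                    samples$sample_id[i])
  }
  clades <- ht_clade_samples(fig_attached)
  all_markers <- names(typed)
  fig_node_of <- function(m) {
    if (m == "V161") return(ht_node_by_name(fig_attached, "A1b"))
    ht_marker_node(fig_attached, m)
  }
  state <- matrix("N", 51L, length(all_markers),
                  dimnames = list(all51, all_markers))
  for (m in all_markers) {
    nd <- fig_node_of(m)
    stopifnot(!is.na(nd))
    ts <- typed[[m]]
    state[ts, m] <- ifelse(ts %in% clades[[nd]], "D", "A")
  }
  raw <- matrix(NA_character_, 51L, length(all_markers),
                dimnames = dimnames(state))
  raw[, "V161"] <- ifelse(all51 %in% clades[[ht_node_by_name(fig_attached, "A1b")]],
                          "C", "G")
  sample_records <- samples[, c("sample_id", "prior_haplogroup", "origin")]
  gm <- genotype_matrix(state, sample_records, raw)

  ## ---- catalog -------------------------------------------------------------
  t1_path <- system.file("extdata", "table1.tsv", package = "ytreemap")
  if (!nzchar(t1_path)) t1_path <- file.path("inst", "extdata", "table1.tsv")
  table1 <- parse_marker_table(t1_path, source_tag = "new-Table1")
  n_other <- length(prior146) + length(backbone59)
  others <- marker_catalog(
    name = c(prior146, backbone59),
    positions = rep(list(NA_integer_), n_other),
    ancestral = NA_character_, derived = NA_character_,
    class = "substitution",
    source_tag = rep(c("prior-146", "backbone-59"),
                     c(length(prior146), length(backbone59))))
  catalog <- rbind(table1, others)
  class(catalog) <- c("marker_catalog", "data.frame")
  validate_marker_catalog(catalog)
  stopifnot(nrow(catalog) == 227L,
            setequal(catalog$name, all_markers))

  ## ---- outgroup table ------------------------------------------------------
  outgroup <- data.frame(
    site = c(table1$name, "V161"),
    allele = c(ifelse(table1$class == "substitution", table1$ancestral, "A"),
               "A"),
    stringsAsFactors = FALSE)
  # deletions have no single-nucleotide outgroup allele; drop them
  outgroup <- outgroup[!outgroup$site %in% c("V303", "V304"), , drop = FALSE]
  rownames(outgroup) <- NULL

  panels <- list(
    A1b_candidates = a1b32, A1b_samples = as.character(1:4),
    A1a_markers = c(a1a20, "M31", "P82", "V147"),
    A1a_samples = as.character(5:6),
    A2_samples = as.character(7:9),
    A3_markers = c(a3_new9, a3_22, "M32", "M28", "M59", "M144", "M190",
                   "P289", "M51", "M13", "M118", "M171"),
    A3_samples = as.character(10:19),
    B_markers = c(b_17, "V254", "V341", "M60", "M181", "P85", "P90", "M236",
                  "M288", "M182", "M150", "M109", "M192", "M112", "M108.1",
                  "50f2(P)", "P6"),
    B_samples = as.character(20:32))

  manifest <- data.frame(
    marker = catalog$name,
    source_tag = catalog$source_tag,
    paper_named = catalog$name %in%
      c(table1$name, "V20", "V45", "V69", "V88", "V104", "V161", "V186",
        "V205", "V218", "V231", "PK1", backbone59),
    stringsAsFactors = FALSE)

  list(backbone = backbone, catalog = catalog, gm = gm, outgroup = outgroup,
       figure_tree = fig_attached, panels = panels, manifest = manifest)
}

#' Write the fixture files to a directory
#'
#' Materializes the packaged fixture as plain-text files: backbone and
#' figure trees (annotated Newick), marker catalog (canonical TSV),
#' genotype matrix with raw-allele companion, and outgroup table.
#'
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- build_paper_fixture()
  paths <- c(
    backbone = file.path(dir, "backbone.nwk"),
    figure_tree = file.path(dir, "figure_tree.nwk"),
    catalog = file.path(dir, "catalog.tsv"),
    matrix = file.path(dir, "genotypes.tsv"),
    raw = file.path(dir, "raw_alleles.tsv"),
    outgroup = file.path(dir, "outgroup.tsv"))
  write_newick_annotated(fx$backbone, paths[["backbone"]])
  write_newick_annotated(fx$figure_tree, paths[["figure_tree"]])
  write_marker_table(fx$catalog, paths[["catalog"]])
  write_genotype_matrix(fx$gm, paths[["matrix"]], paths[["raw"]])
  write_outgroup_table(fx$outgroup, paths[["outgroup"]])
  invisible(paths)
}
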