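# Packaged fixtures: transcriptions of the published specimen lists and
# confusion matrix, plus a synthetic time-scaled composite phylogeny over
# the same taxa (the original composite topology is not machine-readable,
# so the shipped tree nests species by order/family and fossil clades by
# their conventional relationships, with coarse synthetic ages).

#' Load a packaged fixture
#'
#' @param name one of:
#' \describe{
#'   \item{table1_specimens}{87 extant training specimens with order,
#'     family, museum id and flight-mode code (CF/FG/IB/S/PF/SUB, plus one
#'     "SS" entry transcribed verbatim from the source; see
#'     [table1_flight_modes()]).}
#'   \item{table2_mesozoic}{the 26 printed rows of Mesozoic birds and
#'     non-avian theropods (numbering is non-contiguous in the source --
#'     88-115 skipping 90 and 107 -- and is preserved).}
#'   \item{table6_confusion}{6 x 6 cross-classification counts from the
#'     published discriminant analysis; columns = true classes, rows =
#'     predicted.}
#'   \item{composite_tree}{synthetic time-scaled composite phylogeny
#'     (branch lengths in Ma) covering the extant and Mesozoic taxa.}
#' }
#' @return a data.frame, an integer matrix (`table6_confusion`) or a
#'   `phylo` (`composite_tree`).
#' @export
load_fixtures <- function(name = c("table1_specimens", "table2_mesozoic",
                                   "table6_confusion", "composite_tree")) {
  name <- match.arg(name)
  path <- function(f) {
    p <- system.file("extdata", f, package = "furculashape")
    if (!nzchar(p)) stop("fixture file not installed: ", f)
    p
  }
  switch(name,
    table1_specimens = utils::read.csv(path("table1_specimens.csv"),
                                       stringsAsFactors = FALSE,
                                       fileEncoding = "UTF-8"),
    table2_mesozoic = utils::read.csv(path("table2_mesozoic.csv"),
                                      stringsAsFactors = FALSE,
                                      fileEncoding = "UTF-8"),
    table6_confusion = {
      df <- utils::read.csv(path("table6_confusion.csv"),
                            stringsAsFactors = FALSE, check.names = FALSE,
                            fileEncoding = "UTF-8")
      M <- as.matrix(df[, -1L])
      rownames(M) <- df[[1L]]
      storage.mode(M) <- "integer"
      M
    },
    composite_tree = parse_newick(
      paste(readLines(path("composite_tree_synthetic.nwk")),
            collapse = "")))
}

#' Usable flight-mode labels for the training specimens
#'
#' The specimen list carries one "SS" code (the Australasian Darter,
#' *Anhinga novaehollandiae*) where the published abbreviation key defines
#' only CF/FG/IB/S/PF/SUB; the same genus's other species is coded S, so
#' SS is mapped to S here. The verbatim transcription is preserved in the
#' fixture itself.
#'
#' @return named character vector of flight-mode codes by taxon.
#' @export
table1_flight_modes <- function() {
  t1 <- load_fixtures("table1_specimens")
  fm <- t1$flight_mode
  fm[fm == "SS"] <- "S"
  stats::setNames(fm, gsub(" ", "_", t1$taxon))
}

# Build the synthetic composite tree from the fixture tables: species
# nested within families within orders (polytomies), fossil clades in
# their conventional arrangement, time-scaled by equal sharing between
# coarse anchor ages. Used once to generate the shipped Newick fixture;
# exported for reproducibility.

#' Rebuild the synthetic composite phylogeny from the fixture tables
#'
#' @return a time-scaled `phylo` (branch lengths in Ma).
#' @export
build_composite_tree <- function() {
  t1 <- load_fixtures("table1_specimens")
  t2 <- load_fixtures("table2_mesozoic")
  tip <- function(x) gsub("[ .']", "_", x)
  clade_nwk <- function(members) {
    if (length(members) == 1L) members else
      paste0("(", paste(members, collapse = ","), ")")
  }
  # extant: species within families within orders; orders as a basal
  # polytomy of Neornithes
  orders <- split(t1, t1$order)
  order_str <- vapply(orders, function(od) {
    fams <- split(od, od$family)
    clade_nwk(vapply(fams, function(fm) clade_nwk(tip(fm$taxon)),
                     character(1)))
  }, character(1))
  neornithes <- paste0("(", paste(order_str, collapse = ","),
                       ")Neornithes")
  grp <- function(clade) tip(t2$genus[t2$clade == clade])
  ornith <- clade_nwk(c(grp("Ornithuromorpha"), neornithes))
  enant <- clade_nwk(grp("Enantiornithes"))
  crown_ward <- paste0("(", enant, ",", ornith, ")Ornithothoraces")
  basal <- t2$genus[t2$clade == "Basal Aves"]
  aves <- crown_ward
  for (g in rev(tip(basal))) aves <- paste0("(", g, ",", aves, ")")
  aves <- sub("\\)$", ")Aves", aves)
  paraves <- paste0("(", clade_nwk(c(
    tip(t2$genus[t2$clade %in% c("Paraves", "Dromaeosauridae")]))),
    ",", aves, ")Paraves")
  theropoda <- paste0("(", clade_nwk(tip(t2$genus[t2$clade %in%
    c("Therizinosauria", "Therizonosauria", "Oviraptoridae",
      "Tyrannosauridae")])), ",", paraves, ")Theropoda;")
  topo <- parse_newick(theropoda)
  # coarse anchor ages (Ma): fossil tips by epoch midpoint, key nodes dated
  epoch_age <- c(`Late Jurassic` = 150, `Early Cretaceous` = 125,
                 `Late Cretaceous` = 80)
  ages <- stats::setNames(epoch_age[t2$age], tip(t2$genus))
  ages <- c(ages, Theropoda = 235, Paraves = 170, Aves = 160,
            Ornithothoraces = 140, Neornithes = 100)
  scale_to_dates(topo, ages)
}
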