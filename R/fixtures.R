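# Bundled fixtures: hand transcriptions of published comparative maps of the
# avian DCC locus (see inst/extdata/transcription_note.md). Fixtures are
# versioned: every load verifies an md5 checksum.

fixture_md5 <- c(
  "fig3_presence.tsv" = "1052289a0afa87e4ed57e5ee327182d3",
  "genome_chicken.tsv" = "a22e1009be61a6a546cc9d1962e16a0c",
  "genome_guineafowl.tsv" = "b3f1862f9357f6ae98bb1bcb3cc93e91",
  "genome_quail.tsv" = "b3f1862f9357f6ae98bb1bcb3cc93e91",
  "genome_reference.tsv" = "675af3a1663619c738c4231354ad2338",
  "genome_turkey.tsv" = "500764f11f2c6e2c9ce76417f3fb4a57",
  "locus_reference.tsv" = "63c70115d368a9cee3cc9c4cf386f280",
  "table1.tsv" = "f24b3be28ed5a0cdee3ff85d777a005c"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "locusdrift")
  if (p == "") abort(sprintf("fixture file '%s' not found", file))
  got <- unname(tools::md5sum(p))
  want <- fixture_md5[[file]]
  if (!identical(got, want)) {
    abort(sprintf("fixture '%s' failed its checksum (%s != %s)",
                  file, got, want))
  }
  p
}

#' Load a bundled fixture
#'
#' Available fixtures:
#' * `"locus_reference"`: the 31-gene signed reference locus order (7
#'   upstream flank genes, the 17-gene segment `CCDC68`..`MYO5B`, 7
#'   downstream flank genes).
#' * `"genome_reference"`, `"genome_chicken"`, `"genome_quail"`,
#'   `"genome_turkey"`, `"genome_guineafowl"`: gene-order tables.
#' * `"fig3_presence"`: genes-by-species detection matrix with evidence
#'   tiers.
#' * `"table1"`: per-species summary of where the headline gene was found
#'   (assembly top hit, raw reads, transcriptome).
#' * `"galliformes"`: convenience bundle (list with `reference_order`,
#'   `genomes`, `presence`).
#'
#' Every file is checksum-verified on load; see
#' `inst/extdata/transcription_note.md` for provenance and editorial notes.
#'
#' @param name fixture name.
#' @return A tibble, or a list for `"galliformes"`.
#' @export
load_fixture <- function(name = c("locus_reference", "genome_reference",
                                  "genome_chicken", "genome_quail",
                                  "genome_turkey", "genome_guineafowl",
                                  "fig3_presence", "table1", "galliformes")) {
  name <- match.arg(name)
  if (name == "galliformes") {
    return(list(
      reference_order = load_fixture("locus_reference"),
      genomes = list(
        chicken = load_fixture("genome_chicken"),
        quail = load_fixture("genome_quail"),
        turkey = load_fixture("genome_turkey"),
        guineafowl = load_fixture("genome_guineafowl")
      ),
      presence = load_fixture("fig3_presence")
    ))
  }
  file <- paste0(name, ".tsv")
  p <- fixture_path(file)
  if (name == "locus_reference") {
    return(readr::read_tsv(p, show_col_types = FALSE,
                           col_types = readr::cols(gene = "c", strand = "c")))
  }
  if (name %in% c("fig3_presence", "table1")) {
    return(readr::read_tsv(p, show_col_types = FALSE))
  }
  read_genome_table(p)
}

#' Disruption analysis of one fixture species against the reference locus
#'
#' Runs [map_to_reference()], [find_blocks()] and [classify_fates()] for a
#' bundled species and returns the resulting `disruption_report`.
#'
#' @param species one of `"chicken"`, `"quail"`, `"turkey"`,
#'   `"guineafowl"`.
#' @param max_salvage_block scaffold-size bound of the salvage rule.
#' @return A `disruption_report`.
#' @export
fixture_disruption_report <- function(species = c("chicken", "quail",
                                                  "turkey", "guineafowl"),
                                      max_salvage_block = 2) {
  species <- match.arg(species)
  ref <- load_fixture("locus_reference")
  genome <- load_fixture(paste0("genome_", species))
  presence <- load_fixture("fig3_presence") |>
    filter(.data$species == !!species)
  placements <- map_to_reference(ref, genome)
  blocks <- find_blocks(ref, placements)
  classify_fates(ref, placements, presence, blocks, species = species,
                 max_salvage_block = max_salvage_block)
}

#' Worked-example counts from the bundled Galliformes fixtures
#'
#' Recomputes the three headline numbers of the transcribed worked example:
#' the size in genes of the largest disrupted reference segment in chicken,
#' the number of segment genes undetected in all four Galliformes, and the
#' number of genes classified `salvaged` in all four Galliformes.
#'
#' @return List with `disrupted_segment_genes`, `undetected_all_galliformes`,
#'   `salvaged_all_galliformes`, `n_reference_genes`.
#' @export
fixture_counts <- function() {
  galliformes <- c("chicken", "quail", "turkey", "guineafowl")
  ref <- load_fixture("locus_reference")
  pres <- load_fixture("fig3_presence")
  pm <- presence_matrix(pres, gene_order = ref$gene)
  undetected <- undetected_in_all(pm, galliformes)
  reports <- lapply(galliformes, fixture_disruption_report)
  salvaged_sets <- lapply(reports, function(r) {
    r$fates$gene[r$fates$fate == "salvaged"]
  })
  salvaged_all <- Reduce(intersect, salvaged_sets)
  chicken <- reports[[1]]
  list(
    disrupted_segment_genes = chicken$disrupted_segments$n_genes[1],
    undetected_all_galliformes = length(undetected),
    salvaged_all_galliformes = length(salvaged_all),
    n_reference_genes = nrow(ref)
  )
}
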