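fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "surrnet")
  if (p == "") stopf("packaged fixture '%s' is missing or corrupt", file)
  p
}

#' Load the packaged study tables
#'
#' Three small tab-delimited fixtures transcribe the printed tables of the
#' 7-vs-7 ALS skeletal-muscle case-control study the package's defaults
#' emulate: the cohort description (14 samples with ages, sex and biopsy
#' site), the differentially expressed gene list (probe, symbol, raw p,
#' signed linear fold change) and the 100-entry discriminant gene ranking
#' (with mitochondrial / muscle-specific / shared-with-DE-list flags).
#' Decimal commas of the printed originals were normalised to points at
#' fixture-build time; p-values printed as an upper bound ("<0.0001") carry
#' `p_censored = TRUE` and store the bound.  Duplicate symbols and the blank
#' rank-53 entry of the discriminant table are preserved verbatim; counting
#' policy across duplicates is left to the caller.
#'
#' @return A list with data.frames `cohort`, `de_genes` and `discriminant`.
#' @examples
#' tabs <- load_fixture_tables()
#' table(tabs$cohort$group)
#' @export
load_fixture_tables <- function() {
  cohort <- read.delim(fixture_path("table1_cohort.tsv"),
                       stringsAsFactors = FALSE)
  de <- read.delim(fixture_path("table2_de_genes.tsv"),
                   stringsAsFactors = FALSE)
  disc <- read.delim(fixture_path("table3_discriminant.tsv"),
                     stringsAsFactors = FALSE)
  if (nrow(cohort) != 14L || !all(table(cohort$group) == 7L)) {
    stopf("cohort fixture is corrupt: expected 7 samples in each of 2 groups")
  }
  if (!all(seq_len(100) %in% disc$rank)) {
    stopf("discriminant fixture is corrupt: ranks 1..100 required")
  }
  if (any(abs(de$fc) < 2) || any(de$fc == 0)) {
    stopf("DE fixture is corrupt: |FC| >= 2 expected for every printed row")
  }
  list(cohort = cohort, de_genes = de, discriminant = disc)
}

#' Gene sets derived from the discriminant table's annotation flags
#'
#' Builds two gene sets ("mitochondrial", "muscle_specific") from the
#' packaged discriminant-gene fixture, handy as a small worked example for
#' [fisher_enrichment()].
#'
#' @return Named list of character vectors.
#' @export
discriminant_gene_sets <- function() {
  disc <- load_fixture_tables()$discriminant
  disc <- disc[nzchar(disc$gene_symbol), ]
  list(
    mitochondrial = unique(disc$gene_symbol[disc$mitochondrial]),
    muscle_specific = unique(disc$gene_symbol[disc$muscle_specific])
  )
}
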