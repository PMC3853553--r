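# Bundled example data from a published 48-sample fecal metabarcoding
# survey of the red-headed wood pigeon (Ogasawara Islands): the per-taxon
# read counts of the diet table and the per-family structure of the P6-loop
# reference database. Both are small printed tables re-entered as tibbles;
# they serve as worked-example inputs and as fixtures for the frequency and
# discrimination arithmetic.

#' Example diet table: per-taxon read counts from a wood pigeon survey
#'
#' Assigned read counts for the 44 plant taxa detected in 48 fecal samples
#' of the red-headed wood pigeon, with each taxon's native/introduced
#' status. Labels of the form `"Gr. <taxon><k>"` are haplotype groups
#' unresolvable below the named rank. Feeding the `n_reads` column through
#' [frequency_of_reads()] reproduces the published frequency-of-reads
#' percentages (denominator = column sum, 32,288 reads).
#'
#' @return tibble with columns `label`, `origin`, `n_reads`.
#' @export
#' @examples
#' frequency_of_reads(woodpigeon_diet_counts())
woodpigeon_diet_counts <- function() {
  tibble::tribble(
    ~label, ~origin, ~n_reads,
    "Morus australis", "introduced", 11810L,
    "Gr. Lauraceae1", "native", 11280L,
    "Gr. Ficus1", "both", 3902L,
    "Fagara boninsimae", "native", 1328L,
    "Gr. Poaceae2", "introduced", 922L,
    "Ligustrum micranthum", "native", 514L,
    "Leucaena glauca", "introduced", 335L,
    "Sambucus javanica", "introduced", 297L,
    "Carex hattoriana", "native", 231L,
    "Ardisia sieboldii", "native", 226L,
    "Trema orientalis", "native", 212L,
    "Gr. Planchonella1", "native", 158L,
    "Poaceae", "introduced", 115L,
    "Moraceae", "both", 114L,
    "Gr. Palmae2", "both", 90L,
    "Elaeocarpus photiniifolius", "native", 87L,
    "Lantana camara", "introduced", 77L,
    "Buxus liukiuensis", "introduced", 72L,
    "Rhaphiolepis wrightiana", "native", 67L,
    "Solanum nigrum", "introduced", 63L,
    "Juniperus taxifolia", "native", 62L,
    "Calaphyllum inophyllum", "native", 51L,
    "Sonchus oleraceus", "introduced", 43L,
    "Schima mertensiana", "native", 41L,
    "Eurya boninensis", "native", 23L,
    "Celtis boninensis", "native", 21L,
    "Derris elliptica", "introduced", 20L,
    "Hedyotis grayi", "native", 18L,
    "Rutaceae", "native", 17L,
    "Paederia scandens", "introduced", 13L,
    "Livistona chinensis", "native", 10L,
    "Gr. Myrtaceae1", "both", 10L,
    "Scaevola sericea", "native", 9L,
    "Carica papaya", "native", 9L,
    "Pinus luchuensis", "introduced", 7L,
    "Terminalia catappa", "native", 7L,
    "Osmanthus insularis", "native", 6L,
    "Pennisetum purpureum", "introduced", 5L,
    "Drypetes integerrima", "native", 4L,
    "Elaeagnus rotundata", "native", 4L,
    "Melastoma tetramerum", "native", 4L,
    "Paspalum conjugatum", "introduced", 4L,
    "Distylium lepidotum", "native", 0L,
    "Wikstroemia pseudoretusa", "native", 0L
  )
}

#' Example reference structure: species and distinct-sequence counts per family
#'
#' Per-family species counts and distinct P6 sequence counts for the 38
#' multi-species families of an Ogasawara flora reference database of 222
#' species, together with the published within-family discrimination
#' percentage. Four rows of the published table (`Ebenaceae`, `Malvaceae`, `Moraceae`,
#' `Verbenaceae`) are arithmetically inconsistent with
#' `round(100 * n_sequences / n_species)`; the published value is kept
#' as-is in `Rf_published` and flagged in `consistent`.
#'
#' @return tibble with columns `family`, `n_species`, `n_sequences`,
#'   `Rf_published`, `consistent`.
#' @export
woodpigeon_family_structure <- function() {
  x <- tibble::tribble(
    ~family, ~n_species, ~n_sequences, ~Rf_published,
    "Agavaceae", 3L, 2L, 67,
    "Anacardiaceae", 2L, 2L, 100,
    "Apocynaceae", 2L, 2L, 100,
    "Aquifoliaceae", 3L, 1L, 33,
    "Asteraceae", 9L, 8L, 89,
    "Caprifoliaceae", 2L, 2L, 100,
    "Cyperaceae", 12L, 8L, 67,
    "Ebenaceae", 2L, 1L, 33,
    "Euphorbiaceae", 5L, 5L, 100,
    "Fabaceae", 11L, 11L, 100,
    "Lauraceae", 7L, 1L, 14,
    "Liliaceae", 2L, 2L, 100,
    "Malvaceae", 3L, 2L, 50,
    "Melastomataceae", 2L, 1L, 50,
    "Moraceae", 9L, 2L, 20,
    "Myrsinaceae", 3L, 2L, 67,
    "Myrtaceae", 6L, 3L, 50,
    "Nyctaginaceae", 3L, 3L, 100,
    "Oleaceae", 3L, 3L, 100,
    "Palmae", 9L, 3L, 33,
    "Pandanaceae", 2L, 2L, 100,
    "Piperaceae", 2L, 2L, 100,
    "Pittosporaceae", 4L, 1L, 25,
    "Poaceae", 24L, 17L, 71,
    "Ranunculaceae", 2L, 2L, 100,
    "Rosaceae", 4L, 2L, 50,
    "Rubiaceae", 13L, 12L, 92,
    "Rutaceae", 9L, 4L, 44,
    "Sapindaceae", 2L, 2L, 100,
    "Sapotaceae", 3L, 1L, 33,
    "Solanaceae", 3L, 3L, 100,
    "Stachyuraceae", 2L, 1L, 50,
    "Symplocaceae", 2L, 1L, 50,
    "Theaceae", 2L, 2L, 100,
    "Ulmaceae", 2L, 2L, 100,
    "Urticaceae", 2L, 2L, 100,
    "Verbenaceae", 7L, 5L, 75,
    "Zingiberaceae", 3L, 3L, 100
  )
  x$consistent <- x$Rf_published ==
    round_half_up(100 * x$n_sequences / x$n_species)
  x
}
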