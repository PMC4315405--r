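# Shared fixtures: all built in code, nothing downloaded.

write_variant_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "variant_id\tprotein_id\tposition\tref_aa\tvar_aa\tlabel"
  writeLines(c(header, rows), path)
  path
}

# three-term is_a chain A -> B -> C plus a diamond (D has two parents)
toy_obo_text <- function() {
  paste(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:C", "name: rootC", "",
    "[Term]", "id: GO:B", "name: midB", "is_a: GO:C ! rootC", "",
    "[Term]", "id: GO:A", "name: leafA", "is_a: GO:B", "",
    "[Term]", "id: GO:R2", "name: second root", "",
    "[Term]", "id: GO:P1", "name: parent one", "is_a: GO:C", "",
    "[Term]", "id: GO:P2", "name: parent two", "is_a: GO:R2", "",
    "[Term]", "id: GO:D", "name: diamond child",
    "is_a: GO:P1", "is_a: GO:P2", "",
    "[Term]", "id: GO:PO", "name: part-of child",
    "relationship: part_of GO:C", ""
  ), collapse = "\n")
}

# one complete AAindex1 entry, one with an NA, in flat-file layout
aaindex1_fixture <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "H FAKE000001",
    "D synthetic hydropathy-like index (fixture)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5",
    "     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2",
    "//",
    "H FAKE000002",
    "D synthetic index with a missing value (fixture)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.0     2.0     3.0     4.0      NA     6.0     7.0     8.0     9.0    10.0",
    "    11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0",
    "//"), path)
  path
}

# lower-triangular 5x5 substitution matrix entry
aaindex2_fixture <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "H FAKEMAT01",
    "D synthetic lower-triangular substitution matrix (fixture)",
    "M rows = ARNDC, cols = ARNDC",
    "   2.0",
    "  -1.0   3.0",
    "   0.5  -0.5   4.0",
    "   1.5   0.0  -2.0   5.0",
    "  -3.0   1.0   2.5   0.5   6.0",
    "//"), path)
  path
}

# small labelled dataset with planted signal for ensemble tests
signal_dataset <- function(seed = 11, overlap = 0.2, n_proteins = 30,
                           variants_per_protein = 8) {
  generate_dataset(generator_config(
    seed = seed, overlap = overlap, n_proteins = n_proteins,
    variants_per_protein = variants_per_protein,
    informative_features = c("sig1", "sig2"), include_omega = FALSE,
    n_noise_features = 3))
}

smoke_config <- function(seed = 5, n_bootstrap = 15, n_trees = 40) {
  ensemble_config(n_bootstrap = n_bootstrap, n_trees = n_trees, seed = seed)
}
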