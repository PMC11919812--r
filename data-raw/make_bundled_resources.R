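# Regenerates the synthetic bundled resources under inst/extdata from the
# package's own generators. Run from the package root after loading the
# package (pkgload::load_all()).

pkgload::load_all(".", quiet = TRUE)

# 1. idealized synthetic template library (12 templates, 2 per
#    triad-type x topology combination)
lib <- make_template_library(n_per_combo = 2, seed = 202)
save_template_library(lib, "inst/extdata/templates_synthetic",
                      version = "synthetic-1")

# 2. synthetic geometry reference: 250 draws per topology from the
#    generator's dihedral/bond-length distributions
ref <- sample_geometry_reference(n_per_topology = 250, seed = 303)
write_geometry_reference(ref, "inst/extdata/geometry_reference_synthetic.tsv")

# 3. fixture-trained default classifier: the documented Gaussian fixture
#    corpus (positives rmsd~N(0.3,0.1), r_asa~N(0.1,0.05); negatives
#    rmsd~N(1.5,0.2), r_asa~N(0.5,0.1); n=200/200, seed 7)
feats <- withr::with_seed(7, dplyr::bind_rows(
  tibble::tibble(rmsd = rnorm(200, 0.3, 0.1), r_asa = rnorm(200, 0.1, 0.05),
                 label = TRUE),
  tibble::tibble(rmsd = rnorm(200, 1.5, 0.2), r_asa = rnorm(200, 0.5, 0.1),
                 label = FALSE)
))
model <- train_classifier(feats)
model$training_meta$source <- "synthetic-gaussian-fixture"
write_model(model, "inst/extdata/model_synthetic.txt")

message("bundled resources regenerated")
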