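# Fixtures are built in code; nothing is stored on disk.

# Minimal hand-written 3-patient dataset with a 4-gene expression matrix.
toy_dataset <- function() {
  clinical <- data.frame(
    patient_id = c("A", "B", "C"),
    arm = c("ICI", "CHEMO", "ICI"),
    sex = c("male", "female", "male"),
    histology = c("squamous", "nonsquamous", "nonsquamous"),
    smoking = c("ever", "never", "ever"),
    ecog = c(0, 1, 1),
    tmb = c(100, NA, 400),
    pdl1 = c(80, 5, NA),
    pfs_time = c(2.5, 6, 11),
    pfs_event = c(1, 0, 1),
    os_time = c(4, 9, 15),
    os_event = c(1, 0, 0),
    bor_pd = c(1, 0, NA),
    stringsAsFactors = FALSE)
  expr <- matrix(c(1, 2, 3,
                   4, 5, 6,
                   7, 8, 9,
                   0, 0, 0), nrow = 4, byrow = TRUE,
                 dimnames = list(c("G1", "G2", "G3", "G4"),
                                 c("A", "B", "C")))
  trial_dataset(clinical, expr)
}

# Nine-patient cohort with distinct TMB values 10..90 and assorted PD-L1,
# used to exercise cohort-tertile model rules. Upper tertile of TMB is
# 63.33 (type-7), of PD-L1-free signature thresholds as needed.
toy_cohort <- function() {
  data.frame(
    patient_id = sprintf("P%d", 1:9),
    tmb = seq(10, 90, by = 10),
    pdl1 = c(10, 60, 0, 25, 80, 5, 10, 45, 60),
    stringsAsFactors = FALSE)
}

# Deterministic small simulated trial for integration-style tests.
small_trial <- function(scenario = "predictive_only", n = 200,
                        n_genes = 60, seed = 11) {
  sc <- effect_scenarios(n_patients = n, n_genes = n_genes, seed = seed)
  simulate_trial(sc[[scenario]])
}

# Role-named gene sets resolved from a simulated dataset's true blocks.
truth_gene_sets <- function(dataset) {
  gs <- attr(dataset, "truth")$gene_sets
  list(proliferation = gs$proliferation, icr = gs$immune,
       panel = gs$panel, inflammatory = gs$immune,
       lkb1_loss = gs$proliferation, nrf2 = gs$panel,
       neuroendocrine = gs$proliferation)
}
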