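# Shared simulated fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small diverged panel exercised by several modules.
toy_sim <- function() {
  fixture("toy_sim", function() {
    simulate_panel(panel_config(
      n_genomes = 4, n_core = 20,
      accessory_spec = list(c(2, 5)), n_unique_per_genome = 2,
      gene_length = 120, substitution_rate = 0.02, seed = 101
    ))
  })
}

# The 12-genome panel used by the end-to-end recovery checks.
panel12_config <- function() {
  panel_config(
    n_genomes = 12, n_core = 300,
    accessory_spec = list(c(2, 40), c(6, 40), c(11, 20)),
    n_unique_per_genome = 15,
    substitution_rate = 0.02, seed = 20260923
  )
}

panel12_sim <- function() {
  fixture("panel12_sim", function() simulate_panel(panel12_config()))
}

panel12_pipeline <- function() {
  fixture("panel12_pipeline", function() {
    sim <- panel12_sim()
    fams <- infer_ortholog_families(sim$panel)
    pa <- build_presence_absence(
      fams, strains = sort(unique(sim$panel$genes$strain)),
      gene_meta = sim$panel$genes[, c("gene_id", "replicon_class")]
    )
    list(families = fams, pa = pa)
  })
}

# Presence/absence matrix derived directly from the simulation truth
# (bypasses the inference pipeline).
truth_pa_matrix <- function(truth) {
  memb <- truth$membership
  strains <- sort(unique(memb$strain))
  prev <- table(memb$family_id)
  fam_cols <- sort(names(prev)[prev >= 2])
  sing <- memb[memb$family_id %in% names(prev)[prev == 1], ]
  cols <- c(fam_cols, sing$gene_id)
  m <- matrix(0L, length(strains), length(cols),
              dimnames = list(strains, cols))
  fm <- memb[memb$family_id %in% fam_cols, ]
  m[cbind(match(fm$strain, strains), match(fm$family_id, cols))] <- 1L
  m[cbind(match(sing$strain, strains), match(sing$gene_id, cols))] <- 1L
  m
}
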