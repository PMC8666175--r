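# Shared fixtures: small panels and ground truths built in code.

# A 2-protein / 4-peptide panel with equal fragment shares.
small_panel <- function() {
  peps <- c("AAAEEEGGGK", "CCCDDDFFFK", "HHHIIILLLR", "NNNPPPQQQR")
  prots <- c("P1", "P1", "P2", "P2")
  do.call(rbind, lapply(seq_along(peps), function(i) {
    data.frame(protein = prots[i], peptide = peps[i],
               fragment = c("y4", "y5", "y6"), frag_fraction = rep(1 / 3, 3),
               stringsAsFactors = FALSE)
  }))
}

# Noise-free truth: exact ratios, zero background, zero variance components.
noise_free_truth <- function(panel = small_panel()) {
  peptides <- unique(panel$peptide)
  proteins <- unique(panel$protein)
  ground_truth(
    panel = panel,
    slope = setNames(rep(2000, length(peptides)), peptides),
    background_mean = setNames(rep(0, length(peptides)), peptides),
    background_sd = setNames(rep(0, length(peptides)), peptides),
    cv_at_level = c("0.5" = 0, "1000" = 0),
    intra_cv = 0, inter_cv = 0,
    effects = data.frame(protein = proteins, cirrhosis = 0, hcc = 0),
    baseline = setNames(rep(4, length(proteins)), proteins),
    peptide_offset = setNames(rep(0, length(peptides)), peptides),
    noise_sd = 0, subject_sd = 0, tech_sd = 0
  )
}

# Truth with configurable clinical effects/noise on the small panel.
clinical_truth <- function(panel = small_panel(), hcc = c(P1 = -1, P2 = 1),
                           cirr = hcc / 2, noise_sd = 0.3, subject_sd = 0,
                           tech_sd = 0) {
  tr <- noise_free_truth(panel)
  tr$effects <- data.frame(protein = names(hcc), cirrhosis = unname(cirr),
                           hcc = unname(hcc), stringsAsFactors = FALSE)
  tr$noise_sd <- noise_sd
  tr$subject_sd <- subject_sd
  tr$tech_sd <- tech_sd
  tr
}

# Write a transition CSV from text lines and return the path.
write_csv_lines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

transition_header <- paste(mrmquant::transition_columns, collapse = ",")

# Random valid transition table for round-trip property tests.
random_transition_table <- function(n, seed) {
  set.seed(seed)
  peps <- c("AAAEEEGGGK", "CCCDDDFFFK", "HHHIIILLLR")
  grid <- expand.grid(run_id = sprintf("r%02d", 1:10), peptide = peps,
                      fragment = c("y4", "y5"), label = c("light", "heavy"),
                      stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid), n), ]
  data.frame(run_id = grid$run_id, protein = "P1", peptide = grid$peptide,
             precursor_charge = 2L, fragment = grid$fragment,
             label = grid$label, rt_min = runif(n, 10, 50),
             area = ifelse(runif(n) < 0.1, NA, exp(rnorm(n, 10, 2))),
             stringsAsFactors = FALSE)
}
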