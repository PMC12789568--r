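#' Simulate a deconvolution abundance matrix from ground truth
#'
#' Emulates the output of a spot-deconvolution model (absolute cell-type
#' abundances per spot): the true integer cell counts plus Gaussian noise,
#' floored at zero. With the default generator settings the grand mean of
#' cells per spot is 10, matching the deconvolution prior used downstream.
#'
#' @param truth an `"st_ground_truth"` object from [simulate_st_dataset()].
#' @param noise_sd non-negative standard deviation of the additive noise.
#' @param seed integer seed; defaults to the generator seed plus one.
#' @return spots x cell-type numeric matrix (rownames = spot ids).
#' @export
simulate_abundance_matrix <- function(truth, noise_sd = 0.2,
                                      seed = truth$config$seed + 1L) {
  stop_if_not(inherits(truth, "st_ground_truth"),
              "truth must come from simulate_st_dataset()")
  stop_if_not(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd >= 0,
              "noise_sd must be a non-negative scalar")
  cc <- truth$cell_counts
  if (noise_sd == 0) return(cc + 0)
  set.seed(seed)
  pmax(cc + matrix(rnorm(length(cc), sd = noise_sd), nrow = nrow(cc)), 0)
}

variant_fates <- function() {
  c("kept", "fail_consequence", "fail_clinvar", "fail_vaf",
    "fail_popfreq", "fail_panel")
}

#' Simulate an annotated variant table with per-rule fates
#'
#' Each simulated variant is constructed to pass every filtering rule before
#' its assigned first-failing rule (tumor-only cascade order: consequence
#' class, ClinVar benign status, near-homozygous VAF, population frequency,
#' gene panel) and to fail exactly that rule; `kept` variants pass all five.
#'
#' @param n_variants number of variants (> 0).
#' @param rule_mix named proportions over
#'   `c("kept","fail_consequence","fail_clinvar","fail_vaf","fail_popfreq","fail_panel")`,
#'   summing to 1.
#' @param seed integer seed. The fate assignment is the first random draw:
#'   `sample(names(rule_mix), n_variants, TRUE, prob = rule_mix)`.
#' @param panel character vector of panel genes kept by the last rule.
#' @param n_samples number of sample ids to cycle variants over.
#' @return list with `variants` (data.frame: chrom, pos, ref, alt, gene,
#'   consequence, clinvar_class, pop_af, vaf, depth, sample_id) and `truth`
#'   (data.frame: row, fate).
#' @export
simulate_variant_table <- function(n_variants,
                                   rule_mix = setNames(rep(1 / 6, 6),
                                                       variant_fates()),
                                   seed = 1L,
                                   panel = default_aitl_panel(),
                                   n_samples = 4L) {
  stop_if_not(is.numeric(n_variants) && n_variants >= 1,
              "n_variants must be positive")
  stop_if_not(setequal(names(rule_mix), variant_fates()),
              "rule_mix must be named over the six fates")
  stop_if_not(abs(sum(rule_mix) - 1) < 1e-8, "rule_mix must sum to 1")
  rule_mix <- rule_mix[variant_fates()]
  set.seed(seed)
  n <- as.integer(n_variants)
  fate <- sample(names(rule_mix), n, replace = TRUE, prob = rule_mix)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  df <- data.frame(
    chrom = sample(as.character(1:22), n, replace = TRUE),
    pos = sample.int(5e7, n, replace = TRUE),
    ref = ref, alt = alt,
    gene = sample(panel, n, replace = TRUE),
    consequence = sample(c("missense", "stopgain", "frameshift"), n,
                         replace = TRUE),
    clinvar_class = sample(c(NA_character_, "Uncertain significance"), n,
                           replace = TRUE),
    pop_af = ifelse(runif(n) < 0.5, NA_real_, runif(n, 0, 0.009)),
    vaf = runif(n, 0.20, 0.60),
    depth = sample(50:400, n, replace = TRUE),
    sample_id = paste0("AITL", (seq_len(n) - 1L) %% n_samples + 1L),
    stringsAsFactors = FALSE
  )
  i <- fate == "fail_consequence"
  df$consequence[i] <- sample(c("intronic", "synonymous"), sum(i),
                              replace = TRUE)
  i <- fate == "fail_clinvar"
  df$clinvar_class[i] <- sample(c("Benign", "Likely benign",
                                  "Benign/Likely benign"), sum(i),
                                replace = TRUE)
  i <- fate == "fail_vaf"
  df$vaf[i] <- runif(sum(i), 0.901, 0.995)
  i <- fate == "fail_popfreq"
  df$pop_af[i] <- runif(sum(i), 0.011, 0.30)
  i <- fate == "fail_panel"
  df$gene[i] <- paste0("OFFPANEL", sample.int(20, sum(i), replace = TRUE))

  list(variants = df,
       truth = data.frame(row = seq_len(n), fate = fate,
                          stringsAsFactors = FALSE))
}

#' Simulate a two-group survival cohort with IHC marker scores
#'
#' Event-free survival (EFS) and overall survival (OS) times are exponential
#' with a group rate ratio equal to `hazard_ratio` (values below 1 give the
#' uncommon-TME group longer survival; 0.125 is the "eight-fold longer EFS"
#' regime). Marker scores CD68/CD163/CD40LG are Gaussian with group means
#' separated by `marker_sep` standard deviations, oriented so the
#' CD68-high/CD163-high/CD40LG-low rule recovers the true group. Censoring is
#' independent: with probability `censor_rate` a patient is censored at a
#' uniform fraction of their event time.
#'
#' @param n_patients cohort size.
#' @param group_fraction fraction of patients in the uncommon-TME group
#'   (strictly between 0 and 1).
#' @param hazard_ratio positive hazard ratio of uncommon-TME vs other.
#' @param censor_rate probability a patient is censored.
#' @param seed integer seed.
#' @param base_rate baseline exponential event rate per day (other group).
#' @param marker_sep marker mean separation in SD units.
#' @param relapse_probs named probabilities of relapse per group.
#' @return data.frame of patient records: `patient_id`, markers `CD68`,
#'   `CD163`, `CD40LG`, `efs_days`, `efs_event`, `os_days`, `os_event`,
#'   `relapse`, covariates `age`, `sex`, `stage`, and the true group in
#'   `true_group`.
#' @export
simulate_cohort <- function(n_patients, group_fraction = 0.3,
                            hazard_ratio = 0.125, censor_rate = 0.2,
                            seed = 1L, base_rate = 1 / 365,
                            marker_sep = 6,
                            relapse_probs = c(uncommon_TME = 0.2,
                                              other = 0.6)) {
  stop_if_not(n_patients >= 2, "n_patients must be at least 2")
  stop_if_not(group_fraction > 0 && group_fraction < 1,
              "group_fraction must lie strictly between 0 and 1")
  stop_if_not(is.numeric(hazard_ratio) && hazard_ratio > 0,
              "hazard_ratio must be positive")
  stop_if_not(is_proportion(censor_rate), "censor_rate must lie in [0,1]")
  set.seed(seed)
  n <- as.integer(n_patients)
  n_unc <- max(1L, min(n - 1L, round(group_fraction * n)))
  grp <- rep("other", n)
  grp[sample.int(n, n_unc)] <- "uncommon_TME"
  unc <- grp == "uncommon_TME"
  rate <- base_rate * ifelse(unc, hazard_ratio, 1)

  draw_endpoint <- function(rate) {
    t_event <- rexp(n, rate)
    cens <- runif(n) < censor_rate
    time <- ifelse(cens, runif(n) * t_event, t_event)
    list(time = pmax(time, 1e-6), event = as.integer(!cens))
  }
  efs <- draw_endpoint(rate)
  os <- draw_endpoint(rate / 2)

  half <- marker_sep / 2
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    CD68 = rnorm(n, ifelse(unc, half, -half)),
    CD163 = rnorm(n, ifelse(unc, half, -half)),
    CD40LG = rnorm(n, ifelse(unc, -half, half)),
    efs_days = efs$time, efs_event = efs$event,
    os_days = os$time, os_event = os$event,
    relapse = rbinom(n, 1, relapse_probs[grp]),
    age = round(runif(n, 38, 77)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(25, 12)),
    stage = sample(c("III", "IV"), n, replace = TRUE),
    true_group = grp,
    stringsAsFactors = FALSE
  )
}
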