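# Multi-group replicate study designs: abundance matrices with controlled
# fold changes and missingness, and decoy placement.

#' Study design
#'
#' Describes a multi-group replicate experiment. Per-precursor group offsets
#' (true log2 fold changes relative to group 1, the reference) are drawn from
#' Normal(0, `between_group_log2_sd`); per-sample abundances add
#' Normal(0, `within_group_log2_sd`) log2 noise. Missingness can be
#' group-specific (a precursor absent from every replicate of a group) or
#' sample-specific (single cells absent), independently.
#'
#' @param n_groups Number of treatment groups (>= 1); group 1 is the reference.
#' @param n_replicates Replicates per group (>= 1).
#' @param between_group_log2_sd SD of true log2 fold changes (unitless).
#' @param within_group_log2_sd SD of within-group log2 abundance noise.
#' @param prob_missing_group Probability a (precursor, group) pair is entirely
#'   absent.
#' @param prob_missing_sample Probability a single (precursor, sample) cell is
#'   absent.
#' @param fragment_jitter_sd Optional independent per-fragment log2 jitter
#'   applied at MS2 synthesis (default 0: fragment abundances inherit the
#'   precursor's per-sample multiplier unchanged).
#' @param seed Integer seed for the design expansion.
#' @return A `study_design` object.
#' @export
#' @examples
#' study_design(n_groups = 2, n_replicates = 3)
study_design <- function(n_groups = 1L, n_replicates = 1L,
                         between_group_log2_sd = 1.0,
                         within_group_log2_sd = 0.2,
                         prob_missing_group = 0,
                         prob_missing_sample = 0,
                         fragment_jitter_sd = 0,
                         seed = 1L) {
  stopifnot(n_groups >= 1, n_replicates >= 1,
            between_group_log2_sd >= 0, within_group_log2_sd >= 0,
            prob_missing_group >= 0, prob_missing_group <= 1,
            prob_missing_sample >= 0, prob_missing_sample <= 1,
            fragment_jitter_sd >= 0)
  structure(
    list(n_groups = as.integer(n_groups),
         n_replicates = as.integer(n_replicates),
         between_group_log2_sd = between_group_log2_sd,
         within_group_log2_sd = within_group_log2_sd,
         prob_missing_group = prob_missing_group,
         prob_missing_sample = prob_missing_sample,
         fragment_jitter_sd = fragment_jitter_sd,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d group(s) x %d replicate(s); log2 sd between %g / within %g; P(missing) group %g / sample %g; seed %d\n",
    x$n_groups, x$n_replicates, x$between_group_log2_sd,
    x$within_group_log2_sd, x$prob_missing_group, x$prob_missing_sample,
    x$seed))
  invisible(x)
}

#' Sample names of a design
#'
#' @param design A [study_design()].
#' @return Character vector `group{g}_rep{r}` in group-major order.
#' @export
design_samples <- function(design) {
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      group = seq_len(design$n_groups))
  sprintf("group%d_rep%d", grid$group, grid$replicate)
}

#' Expand a library into per-sample abundances
#'
#' For each precursor, draws one true log2 fold change per non-reference group
#' from Normal(0, between-group sd), then per-sample abundances
#' `base_abundance * 2^(group_fc + Normal(0, within-group sd))`. All draws are
#' reproducible from `design$seed`.
#'
#' @param library A precursor library tibble.
#' @param design A [study_design()].
#' @return A long tibble: `precursor_id`, `group`, `replicate`, `sample`,
#'   `true_log2_fc` (0 for group 1), `abundance`, `absent` (all `FALSE`;
#'   see [apply_missingness()]).
#' @export
sample_abundances <- function(library, design) {
  stopifnot(inherits(design, "study_design"))
  n <- nrow(library)
  G <- design$n_groups
  R <- design$n_replicates
  set.seed(design$seed)
  fc <- matrix(0, nrow = n, ncol = G)
  if (G > 1) {
    fc[, -1] <- rnorm(n * (G - 1), 0, design$between_group_log2_sd)
  }
  long <- tidyr::expand_grid(
    precursor_idx = seq_len(n),
    group = seq_len(G),
    replicate = seq_len(R)
  )
  long$precursor_id <- library$precursor_id[long$precursor_idx]
  long$true_log2_fc <- fc[cbind(long$precursor_idx, long$group)]
  noise <- rnorm(nrow(long), 0, design$within_group_log2_sd)
  base <- library$base_abundance[long$precursor_idx]
  tibble::tibble(
    precursor_id = long$precursor_id,
    group = long$group,
    replicate = long$replicate,
    sample = sprintf("group%d_rep%d", long$group, long$replicate),
    true_log2_fc = long$true_log2_fc,
    abundance = base * 2^(long$true_log2_fc + noise),
    absent = FALSE
  )
}

#' Apply group- and sample-specific missingness
#'
#' Independently masks whole (precursor, group) blocks with probability
#' `prob_missing_group` and single (precursor, sample) cells with probability
#' `prob_missing_sample`. Masked cells keep `absent = TRUE` and `NA`
#' abundance; they are excluded from simulation and written as empty fields in
#' the ground truth. Draws use `design$seed + 1` so they do not perturb the
#' abundance stream.
#'
#' @param abundances Output of [sample_abundances()].
#' @param design A [study_design()].
#' @return The abundance tibble with `absent`/`abundance` updated.
#' @export
apply_missingness <- function(abundances, design) {
  stopifnot(inherits(design, "study_design"))
  if (design$prob_missing_group == 0 && design$prob_missing_sample == 0) {
    return(abundances)
  }
  set.seed(design$seed + 1L)
  key_group <- paste(abundances$precursor_id, abundances$group)
  groups <- unique(key_group)
  group_absent <- setNames(runif(length(groups)) < design$prob_missing_group,
                           groups)
  cell_absent <- runif(nrow(abundances)) < design$prob_missing_sample
  absent <- group_absent[key_group] | cell_absent
  abundances$absent <- unname(absent)
  abundances$abundance[absent] <- NA_real_
  abundances
}

#' Place decoy species on the gradient
#'
#' Assigns every decoy a uniform random elution apex inside the usable part of
#' the gradient (`[padding, run_length - padding]`) and a lognormal base
#' abundance from the same family as synthetic precursors. Decoys then
#' participate in MS1 and MS2 synthesis exactly like peptide precursors
#' (fragments gated by precursor-window containment).
#'
#' @param decoys Decoy tibble from [read_msp()].
#' @param gradient A [gradient_model()].
#' @param seed Integer seed (independent of the precursor streams, so a run
#'   without decoys is bit-identical to the same run with an empty decoy set).
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters.
#' @return A library-shaped tibble (`source = "decoy"`) with `apex_rt` set.
#' @export
place_decoys <- function(decoys, gradient, seed = 1L,
                         abundance_meanlog = log(1e5), abundance_sdlog = 1) {
  stopifnot(inherits(gradient, "gradient_model"))
  n <- nrow(decoys)
  empty <- tibble::tibble(
    precursor_id = character(), stripped_sequence = character(),
    modified_sequence = character(), charge = integer(),
    precursor_mz = numeric(), rt_coord = numeric(), rt_basis = character(),
    base_abundance = numeric(), source = character(), fragments = list(),
    apex_rt = numeric()
  )
  if (!n) return(empty)
  set.seed(seed)
  lo <- gradient$padding
  hi <- gradient$run_length - gradient$padding
  tibble::tibble(
    precursor_id = paste0("decoy:", decoys$name),
    stripped_sequence = NA_character_,
    modified_sequence = NA_character_,
    charge = 1L,
    precursor_mz = decoys$precursor_mz,
    rt_coord = NA_real_,
    rt_basis = "assigned",
    base_abundance = rlnorm(n, abundance_meanlog, abundance_sdlog),
    source = "decoy",
    fragments = decoys$fragments,
    apex_rt = runif(n, lo, hi)
  )
}
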