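#' Synthetic cohort configuration
#'
#' Parameters of the generative model used for end-to-end testing. Expression
#' is block-exchangeable Gaussian on the log2 scale: genes are organized into
#' `n_blocks` blocks of `block_size` genes with within-block correlation
#' `rho`; the first `n_causal_blocks` blocks are causal. A latent responder
#' state drives the response: each subject is a responder with probability
#' `activation_rate`, and in responders every causal block activates
#' independently with probability `coactivation` (non-responders have no
#' active blocks). Activation shifts that block's log2 expression by
#' `expr_shift` and raises the subject's Act Area by
#' `effect_size * noise_sd` per active block, on top of Gaussian measurement
#' noise with SD `noise_sd`. Rare activation therefore produces the
#' negatively skewed AUC distribution that eligible drugs show, and the
#' coupled blocks reproduce the redundancy among genomic correlates of a
#' shared sensitivity phenotype that the scoring is designed to exploit. Sparse passenger mutations and
#' recurrent hotspots are added independently of response (set
#' `mutation_effect > 0` to make hotspot carriers respond). An independent
#' unlabeled reference cohort of `n_reference` subjects is drawn from the
#' same law.
#'
#' @param n_subjects labeled cohort size.
#' @param n_genes total genes (block genes first, the rest independent).
#' @param n_blocks,block_size correlated block layout.
#' @param rho within-block exchangeable correlation, `0 <= rho < 1`.
#' @param n_causal_blocks blocks tied to response.
#' @param activation_rate probability that a subject is a responder.
#' @param coactivation probability that each causal block is active in a
#'   responder.
#' @param expr_shift log2 expression shift of an activated block.
#' @param effect_size Act Area shift per active block, in units of
#'   `noise_sd`.
#' @param noise_sd response measurement noise SD (Act Area scale).
#' @param base_act_area baseline Act Area.
#' @param mutation_rate per-gene per-subject background mutation rate.
#' @param hotspots data.frame(gene, protein_change, rate) of recurrent
#'   hotspots; `NULL` for the built-in default pair.
#' @param mutation_effect Act Area shift for hotspot carriers (default 0).
#' @param n_reference reference cohort size.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 400, n_genes = 600, n_blocks = 10,
                       block_size = 15, rho = 0.5, n_causal_blocks = 5,
                       activation_rate = 0.15, coactivation = 0.8,
                       expr_shift = 3.0,
                       effect_size = 1.5, noise_sd = 0.10,
                       base_act_area = 0.05, mutation_rate = 0.004,
                       hotspots = NULL, mutation_effect = 0,
                       n_reference = 200, seed = 1) {
  stopifnot(n_subjects >= 3, n_genes >= n_blocks * block_size,
            rho >= 0, rho < 1, n_causal_blocks <= n_blocks,
            effect_size >= 0, noise_sd > 0, n_reference >= 1)
  if (is.null(hotspots)) {
    hotspots <- data.frame(gene = sprintf("g%04d", n_blocks * block_size + 1:2),
                           protein_change = c("p.G12D", "p.R175H"),
                           rate = c(0.05, 0.04), stringsAsFactors = FALSE)
  }
  structure(mget(names(formals(sim_config))), class = "sim_config")
}

sim_subjects <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

# One cohort draw under the block-exchangeable law; returns log2 expression,
# the activation matrix, and the mutation catalog.
sim_draw <- function(cfg, n, prefix) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  subj <- sim_subjects(prefix, n)
  block_of <- rep(NA_integer_, cfg$n_genes)
  block_of[seq_len(cfg$n_blocks * cfg$block_size)] <-
    rep(seq_len(cfg$n_blocks), each = cfg$block_size)

  z <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
              dimnames = list(genes, subj))
  if (cfg$rho > 0) {
    u <- matrix(stats::rnorm(cfg$n_blocks * n), cfg$n_blocks, n)
    bl <- !is.na(block_of)
    z[bl, ] <- sqrt(cfg$rho) * u[block_of[bl], ] + sqrt(1 - cfg$rho) * z[bl, ]
  }
  responder <- stats::rbinom(n, 1, cfg$activation_rate)
  act <- matrix(stats::rbinom(cfg$n_causal_blocks * n, 1, cfg$coactivation),
                cfg$n_causal_blocks, n,
                dimnames = list(NULL, subj))
  act <- act * rep(responder, each = max(1L, cfg$n_causal_blocks))
  if (cfg$n_causal_blocks == 0L)
    act <- matrix(integer(0), 0L, n, dimnames = list(NULL, subj))
  for (b in seq_len(cfg$n_causal_blocks)) {
    on <- act[b, ] == 1
    if (any(on))
      z[which(block_of == b), on] <- z[which(block_of == b), on] +
        cfg$expr_shift
  }

  # sparse background mutations + recurrent hotspots
  nm <- stats::rbinom(1, cfg$n_genes * n, cfg$mutation_rate)
  classes <- c("missense", "nonsense", "frameshift", "silent")
  muts <- data.frame(subject_id = sample(subj, nm, replace = TRUE),
                     gene = sample(genes, nm, replace = TRUE),
                     protein_change = rep(NA_character_, nm),
                     variant_class = sample(classes, nm, replace = TRUE,
                                            prob = c(.6, .15, .15, .1)),
                     stringsAsFactors = FALSE)
  hs_carriers <- character(0)
  for (h in seq_len(nrow(cfg$hotspots))) {
    carrier <- subj[stats::runif(n) < cfg$hotspots$rate[h]]
    hs_carriers <- union(hs_carriers, carrier)
    if (length(carrier))
      muts <- rbind(muts, data.frame(
        subject_id = carrier, gene = cfg$hotspots$gene[h],
        protein_change = cfg$hotspots$protein_change[h],
        variant_class = "missense", stringsAsFactors = FALSE))
  }
  list(expression = 2^(z + 8), log_expr = z, activation = act,
       responder = responder, muts = muts,
       hotspot_carriers = hs_carriers, subjects = subj)
}

#' Simulate a pharmacogenomic cohort
#'
#' Draws a labeled cohort (expression, mutations, drug response) plus an
#' independent unlabeled reference cohort from the block-structured model
#' described in [sim_config()], together with the ground truth (causal
#' blocks, per-subject activations, expected causal genes).
#'
#' @param cfg `sim_config`.
#' @return list: `expression` (linear-scale matrix genes x subjects),
#'   `mutations` (catalog data.frame), `response` (subject_id, drug_id,
#'   act_area, auc), `truth`, and `reference` (list with `expression`,
#'   `mutations`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(cfg$seed))

  main <- sim_draw(cfg, cfg$n_subjects, "S")
  ref <- sim_draw(cfg, cfg$n_reference, "R")

  n_active <- colSums(main$activation)
  act_area <- cfg$base_act_area +
    cfg$effect_size * cfg$noise_sd * n_active +
    stats::rnorm(cfg$n_subjects, 0, cfg$noise_sd)
  if (cfg$mutation_effect != 0) {
    hit <- main$subjects %in% main$hotspot_carriers
    act_area[hit] <- act_area[hit] + cfg$mutation_effect
  }
  act_area <- pmin(1, pmax(0, act_area))
  response <- data.frame(subject_id = main$subjects, drug_id = "simdrug",
                         act_area = act_area, auc = 1 - act_area,
                         stringsAsFactors = FALSE)
  n_sens_proxy <- sum(n_active > 0)
  if (n_sens_proxy < 2L)
    warning("effect configuration yields fewer than 2 activated subjects")

  causal_genes <- sprintf("g%04d",
                          seq_len(cfg$n_causal_blocks * cfg$block_size))
  truth <- list(causal_blocks = seq_len(cfg$n_causal_blocks),
                activation = main$activation,
                responder = main$responder,
                n_active = n_active,
                causal_genes = causal_genes,
                expected_features = as.vector(outer(
                  causal_genes, paste0("Up_Level", 1:3), paste, sep = "__")))
  list(expression = main$expression, mutations = main$muts,
       response = response, truth = truth,
       reference = list(expression = ref$expression, mutations = ref$muts,
                        activation = ref$activation))
}

#' Random membership dropout (cross-dataset corruption)
#'
#' Deletes each (feature, subject) membership independently with probability
#' `dropout`, emulating per-sample detection loss when a model is carried to
#' a dataset with different sequencing characteristics. Features left empty
#' are removed.
#'
#' @param fs `feature_set`.
#' @param dropout deletion probability in `[0, 1]`.
#' @param seed integer seed.
#' @return corrupted `feature_set`.
#' @export
corrupt_cohort <- function(fs, dropout, seed = 1) {
  stopifnot(inherits(fs, "feature_set"), dropout >= 0, dropout <= 1)
  if (dropout == 0) return(fs)
  if (dropout == 1) return(feature_set())
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  mem <- lapply(fs$members, function(s) s[stats::runif(length(s)) >= dropout])
  feature_set(mem[lengths(mem) > 0L])
}

#' Featurize a simulated cohort
#'
#' Convenience wrapper running the standard featurization pipeline (quantile
#' normalization, fold changes, multi-level DGE features, mutation features)
#' on the output of [simulate_cohort()].
#'
#' @param expression linear-scale expression matrix.
#' @param mutations mutation catalog data.frame.
#' @param config `igsig_config`.
#' @return `feature_set`.
#' @export
featurize_cohort <- function(expression, mutations,
                             config = igsig_config()) {
  fc <- fold_change_matrix(quantile_normalize(expression),
                           trim_frac = config$trim_frac,
                           var_pctl = config$var_pctl)
  combine_features(
    dge_features(fc, max_level = config$max_level),
    mutation_features(mutations, hotspot_min = config$hotspot_min,
                      gene_min = config$gene_min))
}
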