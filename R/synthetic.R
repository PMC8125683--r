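#' Configuration for the synthetic interaction-signature generator
#'
#' The generator emulates what a docking campaign hands the benchmarking
#' framework: a compound-by-protein score matrix plus a drug-indication
#' mapping, with a tunable amount of recoverable signal. Each indication
#' gets a prototype signature drawn i.i.d. Gaussian with standard deviation
#' `signal * noise_sd` per protein; its drugs' signatures are the prototype
#' plus independent `N(0, noise_sd^2)` noise, so `signal` measures cluster
#' separation in units of the within-cluster noise. Background compounds
#' (those with no indication) draw a private prototype the same way, which
#' makes `signal = 0` collapse the whole matrix to i.i.d. noise — the exact
#' null of the hypergeometric control.
#'
#' @param n_compounds Total compound library size.
#' @param n_proteins Number of proteins per signature (default 16, a small
#'   screening sublibrary scale).
#' @param n_indications Number of indications.
#' @param drugs_per_indication Integer, or integer vector of length
#'   `n_indications`, of approved-drug counts (default 4).
#' @param signal Cluster prototype scale in units of `noise_sd` (default 2).
#' @param noise_sd Within-cluster noise standard deviation (default 1).
#' @param overlap Number of additional cross-indication associations: an
#'   existing drug of one indication is also associated with another,
#'   exercising shared-drug analytics (default 0; drug sets are disjoint).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 100, n_proteins = 16,
                             n_indications = 5, drugs_per_indication = 4,
                             signal = 2, noise_sd = 1, overlap = 0,
                             seed = 1L) {
  cfg <- list(
    n_compounds = as.integer(n_compounds),
    n_proteins = as.integer(n_proteins),
    n_indications = as.integer(n_indications),
    drugs_per_indication = as.integer(drugs_per_indication),
    signal = as.numeric(signal),
    noise_sd = as.numeric(noise_sd),
    overlap = as.integer(overlap),
    seed = as.integer(seed)
  )
  if (cfg$n_proteins < 1) abort("need at least one protein")
  if (cfg$n_compounds < 2) abort("need at least two compounds")
  if (cfg$signal < 0) abort("signal must be >= 0")
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0")
  dpi <- cfg$drugs_per_indication
  if (!length(dpi) %in% c(1L, cfg$n_indications)) {
    abort("drugs_per_indication must have length 1 or n_indications")
  }
  if (any(dpi < 2)) abort("each indication needs >= 2 drugs to be benchmarkable")
  sizes <- rep_len(dpi, cfg$n_indications)
  if (sum(sizes) > cfg$n_compounds) {
    abort(paste0("infeasible config: ", sum(sizes), " assigned drugs but only ",
                 cfg$n_compounds, " compounds"))
  }
  cfg$sizes <- sizes
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic screening platform
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `matrix` (an `interaction_matrix`),
#'   `mapping` (an `indication_mapping`) and `config`.
#' @examples
#' p <- generate_platform(synthetic_config(n_compounds = 30, seed = 7))
#' benchmark_pipeline(compute_rankings(p$matrix), p$mapping, c(5, 10))
#' @export
generate_platform <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    ids <- sprintf("C%04d", seq_len(cfg$n_compounds))
    prots <- sprintf("P%03d", seq_len(cfg$n_proteins))
    proto_sd <- cfg$signal * cfg$noise_sd
    # disjoint drug sets, assigned to randomly chosen compounds
    assigned <- sample(ids, sum(cfg$sizes))
    splits <- rep(seq_len(cfg$n_indications), times = cfg$sizes)
    scores <- matrix(NA_real_, cfg$n_compounds, cfg$n_proteins,
                     dimnames = list(ids, prots))
    mapping_rows <- vector("list", cfg$n_indications)
    for (i in seq_len(cfg$n_indications)) {
      drugs <- assigned[splits == i]
      proto <- rnorm(cfg$n_proteins, 0, proto_sd)
      noise <- matrix(rnorm(length(drugs) * cfg$n_proteins, 0, cfg$noise_sd),
                      nrow = length(drugs))
      scores[drugs, ] <- rep(proto, each = length(drugs)) + noise
      mapping_rows[[i]] <- tibble(
        indication_id = sprintf("I%03d", i),
        indication_name = sprintf("synthetic indication %03d", i),
        compound_id = drugs
      )
    }
    background <- setdiff(ids, assigned)
    if (length(background) > 0) {
      # private prototype per background compound = the clusters' marginal
      scores[background, ] <- matrix(
        rnorm(length(background) * cfg$n_proteins, 0,
              sqrt(proto_sd^2 + cfg$noise_sd^2)),
        nrow = length(background)
      )
    }
    mapping <- bind_rows(mapping_rows)
    if (cfg$overlap > 0) {
      extra <- purrr::map(seq_len(cfg$overlap), function(j) {
        ind <- sample(sprintf("I%03d", seq_len(cfg$n_indications)), 1)
        own <- mapping$compound_id[mapping$indication_id == ind]
        pool <- setdiff(assigned, own)
        if (length(pool) == 0) return(NULL)
        tibble(
          indication_id = ind,
          indication_name = mapping$indication_name[mapping$indication_id == ind][1],
          compound_id = sample(pool, 1)
        )
      })
      mapping <- bind_rows(mapping, purrr::compact(extra)) %>% distinct()
    }
    list(
      matrix = interaction_matrix(scores),
      mapping = indication_mapping(mapping),
      config = cfg
    )
  })
}

#' Generate a null platform: i.i.d. signatures, random drug sets
#'
#' The empirical twin of the analytic random control: signatures are i.i.d.
#' standard normal (so all rankings are exchangeable) and indication drug
#' sets of the requested sizes are assigned to uniformly random disjoint
#' compounds. Benchmarking such a platform must agree with
#' [random_control_benchmark()] up to sampling error.
#'
#' @param n_compounds Library size.
#' @param n_proteins Signature length (default 16).
#' @param mapping_shape Integer vector of per-indication drug counts (each
#'   >= 2; their sum at most `n_compounds`).
#' @param seed Integer seed.
#' @return A list with elements `matrix` and `mapping`.
#' @export
generate_null_platform <- function(n_compounds, n_proteins = 16,
                                   mapping_shape = c(2, 3, 5), seed = 1L) {
  cfg <- synthetic_config(
    n_compounds = n_compounds, n_proteins = n_proteins,
    n_indications = length(mapping_shape),
    drugs_per_indication = mapping_shape,
    signal = 0, noise_sd = 1, seed = seed
  )
  out <- generate_platform(cfg)
  out[c("matrix", "mapping")]
}
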