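#' Evolve a nucleotide sequence under the K80 substitution model
#'
#' Mutates `ancestor` so that the expected Kimura 2-parameter distance between
#' ancestor and child equals `d_target`. The continuous-time K80 model with
#' transition/transversion rate ratio `kappa` is solved analytically: for
#' branch length d, the per-site transition probability is
#' P = 1/4 + 1/4 e^{-4bt} - 1/2 e^{-2(at+bt)} and the total transversion
#' probability Q = 1/2 - 1/2 e^{-4bt}, with at = kappa d/(kappa+2) and
#' bt = d/(kappa+2). Plugging the expected P and Q back into the K2P estimator
#' returns exactly d, so the simulated distance is unbiased by construction.
#'
#' @param ancestor character string over A/C/G/T.
#' @param d_target expected K2P distance (substitutions/site), >= 0 and finite.
#' @param kappa transition/transversion rate ratio (default 2).
#' @param seed optional integer; the result is deterministic given the seed.
#' @return mutated character string of the same length.
#' @export
#' @examples
#' evolve_sequence("ACGTACGT", 0)  # identical to the ancestor
evolve_sequence <- function(ancestor, d_target, kappa = 2, seed = NULL) {
  stopifnot(length(ancestor) == 1L, is.character(ancestor))
  if (!is.finite(d_target) || d_target < 0)
    stop("d_target must be finite and >= 0 (no real K80 solution otherwise)",
         call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  v <- strsplit(toupper(ancestor), "", fixed = TRUE)[[1]]
  if (!all(v %in% c("A", "C", "G", "T")))
    stop("ancestor must be over the alphabet {A,C,G,T}", call. = FALSE)
  if (d_target == 0) return(paste(v, collapse = ""))
  bt <- d_target / (kappa + 2)
  at <- kappa * bt
  w <- exp(-4 * bt)
  u <- exp(-2 * (at + bt))
  P <- 0.25 + 0.25 * w - 0.5 * u      # transition probability
  Q <- 0.5 - 0.5 * w                  # total transversion probability
  with_seed(seed, {
    r <- stats::runif(length(v))
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    # each base has two equiprobable transversion targets
    tv1_map <- c(A = "C", G = "C", C = "A", T = "A")
    tv2_map <- c(A = "T", G = "T", C = "G", T = "G")
    out <- v
    i_ts <- r < P
    i_tv1 <- !i_ts & r < P + Q / 2
    i_tv2 <- !i_ts & !i_tv1 & r < P + Q
    out[i_ts] <- ts_map[v[i_ts]]
    out[i_tv1] <- tv1_map[v[i_tv1]]
    out[i_tv2] <- tv2_map[v[i_tv2]]
    paste(out, collapse = "")
  })
}

#' Configuration for a synthetic mother-infant cohort
#'
#' Defines the study design emulated by [generate_cohort()]: families of one
#' mother and one or two infants, longitudinal sampling at fixed timepoint
#' labels, per-entity strain evolution under K80, planted transmission and
#' phage-host co-transmission, and lognormal abundances with a mother/infant
#' compositional offset.
#'
#' @param n_families number of families.
#' @param infants_per_family 1 or 2 infants per family.
#' @param mother_timepoints,infant_timepoints timepoint labels; defaults span
#'   late pregnancy through month 3 for mothers (P3, P7, B, M1, M2, M3) and
#'   the first year for infants (M1, M2, M3, M6, M9, M12).
#' @param n_votus,n_bacteria numbers of viral and bacterial entities.
#' @param transmission_rate probability a strain is transmitted mother->infant
#'   within a family.
#' @param coupling_rate probability a transmitted phage is co-transmitted with
#'   its predicted host (host presence then mirrors the phage exactly).
#' @param seq_length strain sequence length in nucleotides (>= 1000).
#' @param d_within expected K2P distance between longitudinal samples of one
#'   individual.
#' @param d_transmit expected K2P distance between related mother-infant
#'   strains.
#' @param d_unrelated expected K2P distance between strains of different
#'   families.
#' @param kappa transition/transversion rate ratio of the K80 process.
#' @param dropout probability a sample is missing (each individual always
#'   retains at least two samples so longitudinal distances exist).
#' @param presence_rate probability an individual's strain is reconstructed at
#'   a given timepoint (ignored for coupled phages, which copy their host).
#' @param temperate_prob probability a vOTU is temperate.
#' @param mgs_echo probability a viral strain observed by VLP sequencing is
#'   also recovered from the total-metagenome (MGS) sample of the same
#'   individual and timepoint.
#' @param seed integer master seed; all child seeds are derived from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 8L,
                          infants_per_family = 1L,
                          mother_timepoints = c("P3", "P7", "B", "M1", "M2", "M3"),
                          infant_timepoints = c("M1", "M2", "M3", "M6", "M9", "M12"),
                          n_votus = 20L,
                          n_bacteria = 10L,
                          transmission_rate = 0.5,
                          coupling_rate = 0.5,
                          seq_length = 5000L,
                          d_within = 0.002,
                          d_transmit = 0.005,
                          d_unrelated = 0.1,
                          kappa = 2,
                          dropout = 0.1,
                          presence_rate = 0.85,
                          temperate_prob = 0.5,
                          mgs_echo = 0.5,
                          seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              infants_per_family = as.integer(infants_per_family),
              mother_timepoints = mother_timepoints,
              infant_timepoints = infant_timepoints,
              n_votus = as.integer(n_votus),
              n_bacteria = as.integer(n_bacteria),
              transmission_rate = transmission_rate,
              coupling_rate = coupling_rate,
              seq_length = as.integer(seq_length),
              d_within = d_within, d_transmit = d_transmit,
              d_unrelated = d_unrelated, kappa = kappa,
              dropout = dropout, presence_rate = presence_rate,
              temperate_prob = temperate_prob, mgs_echo = mgs_echo,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  probs <- c("transmission_rate", "coupling_rate", "dropout",
             "presence_rate", "temperate_prob", "mgs_echo")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("%s must lie in [0, 1]", p), call. = FALSE)
  }
  if (cfg$seq_length < 1000L)
    stop("seq_length must be >= 1000", call. = FALSE)
  if (!(cfg$d_within <= cfg$d_transmit && cfg$d_transmit < cfg$d_unrelated))
    stop("distances must satisfy d_within <= d_transmit < d_unrelated",
         call. = FALSE)
  if (cfg$n_families < 1L || cfg$n_votus < 1L || cfg$n_bacteria < 1L)
    stop("n_families, n_votus and n_bacteria must be >= 1", call. = FALSE)
  if (length(cfg$mother_timepoints) == 0L || length(cfg$infant_timepoints) == 0L)
    stop("each role needs at least one timepoint", call. = FALSE)
  if (!cfg$infants_per_family %in% c(1L, 2L))
    stop("infants_per_family must be 1 or 2", call. = FALSE)
  invisible(cfg)
}

# Age in days for the timepoint labels used by the generator. For mothers,
# ages are centred on delivery (negative during pregnancy).
timepoint_age_days <- function(labels) {
  map <- c(P3 = -196, P7 = -84, B = 0,
           M1 = 30, M2 = 61, M3 = 91, M6 = 182, M9 = 274, M12 = 365)
  unname(map[labels])
}

random_dna <- function(n, seed = NULL) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds a complete input bundle for the pipeline: sample metadata, a
#' breadth/count coverage table, a breadth-filtered RPKM abundance matrix,
#' scaffold annotations that pass the viral curation rules, per-entity strain
#' alignments evolved under K80, a virus->host map, and a truth table of
#' planted transmission and co-transmission events.
#'
#' Strains are evolved on a star-like genealogy: each entity has one ancestor;
#' each family's maternal base strain sits at distance `d_unrelated/2` from
#' it (so unrelated pairs are ~`d_unrelated` apart); a transmitted infant base
#' strain is evolved from the maternal base at distance `d_transmit`; a
#' non-transmitted infant gets an independent base at `d_unrelated/2`; each
#' longitudinal sample drifts `d_within/2` from its individual's base. When a
#' phage is coupled to its predicted host, the host is transmitted in the same
#' families and the phage strain is present exactly in the individual-timepoints
#' where the host strain is present.
#'
#' @param config a [cohort_config()].
#' @return list of class `cohort` with elements `samples`, `coverage`,
#'   `abundance`, `annotations`, `alignments` (list with `virus` and
#'   `bacteria`, each a named list of named character vectors),
#'   `host_map`, `truth`, `lifestyle`, and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  ctr <- 0L
  next_seed <- function() {
    ctr <<- ctr + 1L
    child_seed(cfg$seed, ctr)
  }

  ## ---- individuals and samples -------------------------------------------
  fams <- sprintf("F%02d", seq_len(cfg$n_families))
  individuals <- do.call(rbind, lapply(fams, function(f) {
    inf <- sprintf("%s_I%d", f, seq_len(cfg$infants_per_family))
    data.frame(individual_id = c(sprintf("%s_M", f), inf),
               family_id = f,
               role = c("mother", rep("infant", cfg$infants_per_family)),
               stringsAsFactors = FALSE)
  }))

  sample_rows <- do.call(rbind, lapply(seq_len(nrow(individuals)), function(i) {
    ind <- individuals[i, ]
    tps <- if (ind$role == "mother") cfg$mother_timepoints else cfg$infant_timepoints
    expand.grid(individual_id = ind$individual_id, timepoint = tps,
                source = c("VLP", "TOTAL"), stringsAsFactors = FALSE)
  }))
  sample_rows <- merge(sample_rows, individuals, by = "individual_id", sort = FALSE)
  sample_rows$sample_id <- sprintf("%s_%s_%s", sample_rows$individual_id,
                                   sample_rows$timepoint, sample_rows$source)
  sample_rows$age_days <- timepoint_age_days(sample_rows$timepoint)

  # dropout at the individual-timepoint level; keep >= 2 timepoints each
  keep_tp <- with_seed(next_seed(), {
    lapply(split(sample_rows, sample_rows$individual_id), function(df) {
      tps <- unique(df$timepoint)
      keep <- tps[stats::runif(length(tps)) >= cfg$dropout]
      if (length(keep) < 2L) keep <- sample(tps, min(2L, length(tps)))
      keep
    })
  })
  sample_rows <- sample_rows[mapply(function(ind, tp) tp %in% keep_tp[[ind]],
                                    sample_rows$individual_id,
                                    sample_rows$timepoint), ]

  samples <- with_seed(next_seed(), data.frame(
    sample_id = sample_rows$sample_id,
    individual_id = sample_rows$individual_id,
    family_id = sample_rows$family_id,
    role = sample_rows$role,
    timepoint = sample_rows$timepoint,
    age_days = sample_rows$age_days,
    source = sample_rows$source,
    library_size = round(stats::rlnorm(nrow(sample_rows), log(5e6), 0.3)),
    dna_conc = round(stats::rlnorm(nrow(sample_rows), log(10), 0.5), 2),
    stringsAsFactors = FALSE))
  rownames(samples) <- NULL

  ## ---- entities, truth, host map -----------------------------------------
  votus <- sprintf("vOTU_%03d", seq_len(cfg$n_votus))
  bacts <- sprintf("bact_%03d", seq_len(cfg$n_bacteria))

  host_map <- with_seed(next_seed(), data.frame(
    virus_id = votus,
    host_id = sample(bacts, cfg$n_votus, replace = TRUE),
    confidence = round(stats::runif(cfg$n_votus, 0.5, 1), 3),
    stringsAsFactors = FALSE))

  # transmission / coupling draws, per entity x family
  truth_v <- with_seed(next_seed(), {
    do.call(rbind, lapply(votus, function(v) {
      trans <- stats::runif(cfg$n_families) < cfg$transmission_rate
      coupled <- trans & (stats::runif(cfg$n_families) < cfg$coupling_rate)
      data.frame(entity_id = v, kind = "virus", family_id = fams,
                 transmitted = trans,
                 coupled_host_id = ifelse(coupled,
                                          host_map$host_id[host_map$virus_id == v],
                                          NA_character_),
                 stringsAsFactors = FALSE)
    }))
  })
  truth_b <- with_seed(next_seed(), {
    do.call(rbind, lapply(bacts, function(b) {
      data.frame(entity_id = b, kind = "bacterium", family_id = fams,
                 transmitted = stats::runif(cfg$n_families) < cfg$transmission_rate,
                 coupled_host_id = NA_character_,
                 stringsAsFactors = FALSE)
    }))
  })
  # coupling forces the host to be transmitted in the same family
  forced <- unique(truth_v[!is.na(truth_v$coupled_host_id),
                           c("coupled_host_id", "family_id")])
  if (nrow(forced) > 0L) {
    idx <- match(paste(forced$coupled_host_id, forced$family_id),
                 paste(truth_b$entity_id, truth_b$family_id))
    truth_b$transmitted[idx] <- TRUE
  }
  truth <- rbind(truth_v, truth_b)
  rownames(truth) <- NULL

  lifestyle <- with_seed(next_seed(),
    stats::setNames(ifelse(stats::runif(cfg$n_votus) < cfg$temperate_prob,
                           "temperate", "virulent"), votus))

  ## ---- strain evolution ---------------------------------------------------
  # presence draws per entity x individual x timepoint; coupled phages copy
  # the host's presence pattern at shared timepoints
  ind_tp <- unique(samples[, c("individual_id", "family_id", "role", "timepoint")])

  presence_for <- function(seed) {
    with_seed(seed, stats::runif(nrow(ind_tp)) < cfg$presence_rate)
  }

  evolve_entity <- function(entity, kind, host_presence = NULL) {
    tr <- truth[truth$entity_id == entity, ]
    anc <- random_dna(cfg$seq_length, next_seed())
    pres <- if (is.null(host_presence)) presence_for(next_seed()) else host_presence
    seqs <- character(0)
    for (f in fams) {
      fam_rows <- which(ind_tp$family_id == f)
      mother_id <- individuals$individual_id[individuals$family_id == f &
                                               individuals$role == "mother"]
      infant_ids <- individuals$individual_id[individuals$family_id == f &
                                                individuals$role == "infant"]
      mother_base <- evolve_sequence(anc, cfg$d_unrelated / 2, cfg$kappa, next_seed())
      transmitted <- tr$transmitted[tr$family_id == f]
      bases <- c(stats::setNames(list(mother_base), mother_id),
                 stats::setNames(lapply(infant_ids, function(i) {
                   if (transmitted)
                     evolve_sequence(mother_base, cfg$d_transmit, cfg$kappa, next_seed())
                   else
                     evolve_sequence(anc, cfg$d_unrelated / 2, cfg$kappa, next_seed())
                 }), infant_ids))
      for (r in fam_rows) {
        if (!pres[r]) next
        ind <- ind_tp$individual_id[r]
        s <- evolve_sequence(bases[[ind]], cfg$d_within / 2, cfg$kappa, next_seed())
        seqs[sprintf("%s_%s", ind, ind_tp$timepoint[r])] <- s
      }
    }
    list(seqs = seqs, presence = pres)
  }

  # bacteria first so coupled phages can mirror their host's presence
  bact_strains <- stats::setNames(lapply(bacts, function(b)
    evolve_entity(b, "bacterium")), bacts)

  virus_strains <- stats::setNames(lapply(votus, function(v) {
    host <- host_map$host_id[host_map$virus_id == v]
    fam_coupled <- !is.na(truth_v$coupled_host_id[truth_v$entity_id == v])
    base_pres <- presence_for(next_seed())
    host_pres <- bact_strains[[host]]$presence
    pres <- ifelse(fam_coupled[match(ind_tp$family_id, fams)],
                   host_pres, base_pres)
    evolve_entity(v, "virus", host_presence = pres)
  }), votus)

  # map strain sequences (keyed by individual_timepoint) onto sample records
  aln_for <- function(strains, src_priority) {
    keys <- sprintf("%s_%s", samples$individual_id, samples$timepoint)
    out <- list()
    for (e in names(strains)) {
      seqs <- strains[[e]]$seqs
      hit <- samples$source %in% src_priority & keys %in% names(seqs)
      if (!any(hit)) next
      rec <- stats::setNames(seqs[keys[hit]], samples$sample_id[hit])
      out[[e]] <- rec
    }
    out
  }
  virus_aln <- aln_for(virus_strains, c("VLP"))
  # optional MGS echoes of viral strains
  virus_aln <- with_seed(next_seed(), {
    keys <- sprintf("%s_%s", samples$individual_id, samples$timepoint)
    for (e in names(virus_aln)) {
      seqs <- virus_strains[[e]]$seqs
      hit <- which(samples$source == "TOTAL" & keys %in% names(seqs) &
                     stats::runif(nrow(samples)) < cfg$mgs_echo)
      if (length(hit) > 0L)
        virus_aln[[e]] <- c(virus_aln[[e]],
                            stats::setNames(seqs[keys[hit]], samples$sample_id[hit]))
    }
    virus_aln
  })
  bact_aln <- aln_for(bact_strains, c("TOTAL"))

  ## ---- coverage and abundance --------------------------------------------
  scaffold_len <- with_seed(next_seed(),
    stats::setNames(round(stats::runif(cfg$n_votus, 3500, 60000)), votus))
  vlp <- samples[samples$source == "VLP", ]
  keys_vlp <- sprintf("%s_%s", vlp$individual_id, vlp$timepoint)
  coverage <- with_seed(next_seed(), {
    base_mean <- stats::setNames(stats::rnorm(cfg$n_votus, 3, 1), votus)
    # per-vOTU infant shift: mother and infant viromes differ in composition,
    # not just in depth
    infant_shift <- stats::setNames(stats::rnorm(cfg$n_votus, -0.5, 1), votus)
    rows <- lapply(votus, function(v) {
      present <- keys_vlp %in% names(virus_strains[[v]]$seqs)
      offset <- ifelse(vlp$role == "infant", unname(infant_shift[v]), 0)
      mu <- unname(base_mean[v]) + offset
      count <- ifelse(present,
                      pmax(1, round(stats::rlnorm(nrow(vlp), mu, 0.8) *
                                      unname(scaffold_len[v]) / 1000)),
                      0)
      breadth <- ifelse(present, stats::runif(nrow(vlp), 0.955, 1),
                        stats::runif(nrow(vlp), 0, 0.3))
      breadth[count == 0] <- 0
      data.frame(scaffold_id = v, sample_id = vlp$sample_id,
                 read_count = count, breadth = round(breadth, 4),
                 scaffold_length = unname(scaffold_len[v]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(coverage) <- NULL

  lib <- stats::setNames(samples$library_size, samples$sample_id)
  abundance <- rpkm_transform(apply_breadth_filter(coverage), lib[vlp$sample_id])

  ## ---- scaffold annotations ----------------------------------------------
  annotations <- with_seed(next_seed(), {
    n <- cfg$n_votus
    circ <- stats::runif(n) < 0.4
    vs <- stats::runif(n) < 0.7
    pvog <- stats::rpois(n, 6) + 3L
    data.frame(
      scaffold_id = votus,
      length_bp = unname(scaffold_len),
      circular = circ,
      virsorter_positive = vs | !circ,  # every vOTU passes >= 1 criterion
      pvog_hits = pvog,
      pvog_per_10kb = round(pvog / (unname(scaffold_len) / 1e4), 3),
      ribosomal_protein_genes = 0L,
      rrna_hit = FALSE,
      refseq_viral_hit = stats::runif(n) < 0.3,
      crass_hit = stats::runif(n) < 0.05,
      nt_hit = FALSE,
      vc_id = sprintf("VC_%03d", seq_len(n)),
      negctrl_cluster = FALSE,
      checkv_quality = sample(c("Complete", "High-quality"), n, replace = TRUE),
      integrase = lifestyle == "temperate",
      recombinase = FALSE,
      ci_repressor = FALSE,
      stringsAsFactors = FALSE)
  })
  rownames(annotations) <- NULL

  structure(list(samples = samples, coverage = coverage, abundance = abundance,
                 annotations = annotations,
                 alignments = list(virus = virus_aln, bacteria = bact_aln),
                 host_map = host_map, truth = truth, lifestyle = lifestyle,
                 config = cfg),
            class = "cohort")
}
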