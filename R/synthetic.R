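# Synthetic multi-forest root-sampling datasets with controllable host
# specificity, guild structure, nestedness and read noise. The generator
# emulates the sampling design the pipeline is meant for: several forests,
# a few hundred root samples per forest, uneven plant abundances, >1000
# fungal OTUs spread over guilds, over-dispersed read depths that exercise
# the rarefaction drop path, and rare contamination reads that exercise the
# 0.1% entry filter.

# Guild compatibility: mycorrhizal fungi require hosts of their symbiosis
# type (DUAL plants host both); saprotrophic/endophytic, pathogenic and
# unassigned fungi can associate with any plant.
.compatible <- function(plantType, guild) {
  switch(guild,
    AM = plantType %in% c("AM_PLANT", "DUAL"),
    ECM = plantType %in% c("ECM_PLANT", "DUAL"),
    TRUE
  )
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults emulate a multi-forest root-sampling design: 8 forests, 383
#' root samples collected per forest, 17-55 plant species/taxa per forest
#' drawn from a 55-taxon pool with geometric (few dominant, many rare)
#' abundances, and 1120 fungal OTUs spread over the five guilds. Read
#' depths are negative-binomial with mean 1500 so that rarefaction to 1000
#' reads drops a realistic fraction of samples, and each sample receives a
#' Poisson number of spurious single-read contamination entries.
#'
#' @param n_forests Number of forests.
#' @param n_samples Root samples collected per forest.
#' @param n_plants Plant species/taxa per forest; `NULL` (default) draws a
#'   number between 17 and 55 independently per forest.
#' @param plant_type_probs Named probabilities of mycorrhizal types in the
#'   plant pool.
#' @param otu_counts Named integer vector of OTUs per guild.
#' @param specialization_alpha Dirichlet concentration of a plant's
#'   affinity over its compatible OTUs; small values give specialized
#'   plants (dimensionless, > 0).
#' @param generalism_gamma Exponent of the power-law generalism weights of
#'   OTUs; larger values spread OTU popularity more unevenly.
#' @param breadth_range Range (fractions of the compatible OTU set) of
#'   per-plant host breadths; `c(1, 1)` (default) gives every plant access
#'   to its full compatible set, while a wide range such as `c(0.15, 1)`
#'   produces nested association structure (narrow-breadth plants use
#'   subsets of the popular OTUs that broad-breadth plants use).
#' @param block_structure If `TRUE`, plants and OTUs are partitioned into
#'   `n_blocks` compartments and affinities are confined within
#'   compartments — the anti-nested, host-differentiated regime.
#' @param n_blocks Number of compartments when `block_structure` is on.
#' @param guild_leakage_eps Probability mass a plant places outside its
#'   compatible (and block) OTU set, in `[0, 1]`.
#' @param mean_reads,reads_dispersion Negative-binomial mean and size of
#'   per-sample read totals (before contamination).
#' @param contamination_rate Expected number of spurious single-read OTU
#'   entries per sample (Poisson).
#' @param abundance_ratio Ratio of the geometric series of plant relative
#'   abundances.
#' @param exchangeable If `TRUE`, every plant shares one common affinity
#'   vector (fungal composition independent of the host), so the
#'   host-label-shuffle null model is exactly true; see
#'   [exchangeableConfig()].
#' @param seed Default seed used by [generateDataset()].
#' @return A validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(n_forests = 8,
                            n_samples = 383,
                            n_plants = NULL,
                            plant_type_probs = c(AM_PLANT = 0.55,
                                                 ECM_PLANT = 0.25,
                                                 NM_PLANT = 0.12,
                                                 DUAL = 0.08),
                            otu_counts = c(AM = 150, ECM = 250,
                                           SAPENDO = 400, PATHO = 20,
                                           UNKNOWN = 300),
                            specialization_alpha = 1,
                            generalism_gamma = 1,
                            breadth_range = c(1, 1),
                            block_structure = FALSE,
                            n_blocks = 4,
                            guild_leakage_eps = 0.05,
                            mean_reads = 1500,
                            reads_dispersion = 5,
                            contamination_rate = 2,
                            abundance_ratio = 0.9,
                            exchangeable = FALSE,
                            seed = NULL) {
  stopifnot(
    n_forests >= 1, n_samples >= 1,
    is.null(n_plants) || n_plants >= 2,
    all(names(otu_counts) %in% .GUILDS),
    all(otu_counts >= 0), sum(otu_counts) >= 2,
    specialization_alpha > 0, generalism_gamma >= 0,
    length(breadth_range) == 2L, breadth_range[1] > 0,
    breadth_range[1] <= breadth_range[2], breadth_range[2] <= 1,
    guild_leakage_eps >= 0, guild_leakage_eps <= 1,
    mean_reads >= 1, reads_dispersion > 0, contamination_rate >= 0,
    abundance_ratio > 0, abundance_ratio <= 1,
    abs(sum(plant_type_probs) - 1) < 1e-8,
    all(names(plant_type_probs) %in% .PLANT_TYPES)
  )
  structure(list(
    n_forests = as.integer(n_forests),
    n_samples = as.integer(n_samples),
    n_plants = if (is.null(n_plants)) NULL else as.integer(n_plants),
    plant_type_probs = plant_type_probs,
    otu_counts = otu_counts,
    specialization_alpha = specialization_alpha,
    generalism_gamma = generalism_gamma,
    breadth_range = breadth_range,
    block_structure = isTRUE(block_structure),
    n_blocks = as.integer(n_blocks),
    guild_leakage_eps = guild_leakage_eps,
    mean_reads = mean_reads,
    reads_dispersion = reads_dispersion,
    contamination_rate = contamination_rate,
    abundance_ratio = abundance_ratio,
    exchangeable = isTRUE(exchangeable),
    seed = seed
  ), class = "syntheticConfig")
}

#' Make a configuration exchangeable (host-independent fungi)
#'
#' Returns a copy of `base` in which every plant shares one common affinity
#' vector, so the fungal composition of a sample is independent of its host
#' plant label and the host-label-shuffle null model holds exactly. Under
#' such a configuration `specialization_alpha`, `breadth_range` and
#' `block_structure` have no effect on the output distribution.
#'
#' @param base A [syntheticConfig()].
#' @return A `syntheticConfig` with `exchangeable = TRUE`.
#' @export
exchangeableConfig <- function(base) {
  stopifnot(inherits(base, "syntheticConfig"))
  base$exchangeable <- TRUE
  base
}

# Per-forest affinity matrix (plants x OTUs, rows sum to 1).
.forestAffinity <- function(cfg, plantTypes, guilds, w) {
  np <- length(plantTypes)
  no <- length(guilds)
  if (cfg$exchangeable) {
    shared <- w / sum(w)
    aff <- matrix(rep(shared, each = np), np, no)
    return(aff)
  }
  blockP <- (seq_len(np) - 1L) %% cfg$n_blocks
  blockO <- (seq_len(no) - 1L) %% cfg$n_blocks
  aff <- matrix(0, np, no)
  for (p in seq_len(np)) {
    compat <- vapply(guilds, .compatible, logical(1), plantType = plantTypes[p])
    if (cfg$block_structure) compat <- compat & (blockO == blockP[p])
    if (any(compat) && cfg$breadth_range[1] < 1) {
      b <- runif(1, cfg$breadth_range[1], cfg$breadth_range[2])
      idx <- which(compat)
      keep <- idx[order(w[idx], decreasing = TRUE)][seq_len(ceiling(b * length(idx)))]
      compat[] <- FALSE
      compat[keep] <- TRUE
    }
    if (!any(compat) && cfg$guild_leakage_eps == 0)
      stop("infeasible config: plant of type ", plantTypes[p],
           " has no compatible OTUs and zero leakage", call. = FALSE)
    row <- numeric(no)
    if (any(compat)) {
      g <- rgamma(sum(compat), shape = cfg$specialization_alpha, rate = 1)
      g[g < 1e-12] <- 1e-12
      base <- w[compat] * g
      row[compat] <- (1 - cfg$guild_leakage_eps) * base / sum(base)
    }
    if (any(!compat) && cfg$guild_leakage_eps > 0) {
      leakMass <- if (any(compat)) cfg$guild_leakage_eps else 1
      row[!compat] <- leakMass * w[!compat] / sum(w[!compat])
    }
    aff[p, ] <- row / sum(row)
  }
  aff
}

.taxonomyFor <- function(guild, i) {
  phylum <- switch(guild, AM = "Glomeromycota", ECM = "Basidiomycota",
                   PATHO = "Ascomycota", SAPENDO = "Ascomycota",
                   "unidentified")
  sprintf("Fungi;%s;unidentified;unidentified;unidentified;genus_%04d",
          phylum, i)
}

#' Generate a synthetic multi-forest dataset
#'
#' Draws, for every forest, the host plant of each root sample from the
#' forest's (geometric) plant abundances, an over-dispersed read total, and
#' multinomial OTU read counts from the plant's affinity row; the affinity
#' combines the guild compatibility mask (with leakage
#' `guild_leakage_eps`), per-plant Dirichlet(`specialization_alpha`) draws,
#' power-law OTU generalism weights, optional per-plant host breadths, and
#' optional block compartments. Contamination adds a Poisson number of
#' spurious single-read entries per sample. Fully reproducible from `seed`.
#'
#' @param cfg A [syntheticConfig()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A list with elements `tables` (list of [SampleTable], one per
#'   forest), `otu_annotations`, `plant_annotations` (data.frames in the
#'   [readAnnotations()] schema), and `ground_truth` (per-forest affinity
#'   matrices, per-sample true plant labels, and the config).
#' @export
generateDataset <- function(cfg = syntheticConfig(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  if (is.null(seed)) stop("a seed is required", call. = FALSE)

  nOtu <- sum(cfg$otu_counts)
  otuIds <- sprintf("otu_%04d", seq_len(nOtu))
  guilds <- rep(names(cfg$otu_counts), cfg$otu_counts)

  poolSize <- if (is.null(cfg$n_plants)) 55L else cfg$n_plants
  plantIds <- sprintf("plant_%02d", seq_len(poolSize))

  pool <- withSeed(childSeed(seed, "pool"), {
    types <- sample(names(cfg$plant_type_probs), poolSize, replace = TRUE,
                    prob = cfg$plant_type_probs)
    # generalism ranks are assigned by a random permutation so popularity
    # is not confounded with guild order
    rank <- sample.int(nOtu)
    w <- rank^(-cfg$generalism_gamma)
    list(types = types, w = w)
  })

  otuAnn <- data.frame(
    otu_id = otuIds,
    taxonomy = vapply(seq_len(nOtu),
                      function(i) .taxonomyFor(guilds[i], i), character(1)),
    guild = guilds, stringsAsFactors = FALSE
  )
  plantAnn <- data.frame(plant_label = plantIds,
                         mycorrhizal_type = pool$types,
                         stringsAsFactors = FALSE)

  tables <- vector("list", cfg$n_forests)
  affinities <- vector("list", cfg$n_forests)
  truthLabels <- vector("list", cfg$n_forests)
  for (f in seq_len(cfg$n_forests)) {
    fid <- sprintf("F%d", f)
    res <- withSeed(childSeed(seed, paste0("forest:", f)), {
      np <- if (is.null(cfg$n_plants)) sample(17:55, 1L) else cfg$n_plants
      np <- min(np, poolSize)
      sel <- sort(sample.int(poolSize, np))
      ab <- cfg$abundance_ratio^(seq_len(np) - 1)
      ab <- ab / sum(ab)
      aff <- .forestAffinity(cfg, pool$types[sel], guilds, pool$w)
      rownames(aff) <- plantIds[sel]
      colnames(aff) <- otuIds

      plantIdx <- sample.int(np, cfg$n_samples, replace = TRUE, prob = ab)
      depth <- rnbinom(cfg$n_samples, size = cfg$reads_dispersion,
                       mu = cfg$mean_reads)
      counts <- matrix(0L, cfg$n_samples, nOtu,
                       dimnames = list(sprintf("%s_s%03d", fid,
                                               seq_len(cfg$n_samples)),
                                       otuIds))
      for (s in seq_len(cfg$n_samples)) {
        if (depth[s] > 0)
          counts[s, ] <- rmultinom(1L, depth[s], aff[plantIdx[s], ])[, 1L]
      }
      if (cfg$contamination_rate > 0) {
        nSpur <- rpois(cfg$n_samples, cfg$contamination_rate)
        for (s in seq_len(cfg$n_samples)) {
          if (nSpur[s] > 0) {
            idx <- sample.int(nOtu, min(nSpur[s], nOtu))
            counts[s, idx] <- counts[s, idx] + 1L
          }
        }
      }
      list(counts = counts, labels = plantIds[sel][plantIdx], aff = aff)
    })
    tables[[f]] <- SampleTable(res$counts, res$labels, fid)
    affinities[[f]] <- res$aff
    truthLabels[[f]] <- res$labels
    names(tables)[f] <- names(affinities)[f] <- names(truthLabels)[f] <- fid
  }

  list(
    tables = tables,
    otu_annotations = otuAnn,
    plant_annotations = plantAnn,
    ground_truth = list(affinity = affinities, plant_labels = truthLabels,
                        config = cfg)
  )
}
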