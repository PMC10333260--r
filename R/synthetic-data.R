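#' @include AllClasses.R interactome-io.R
NULL

#' Simulation configuration
#'
#' Seeded configuration for every synthetic-data generator. The defaults
#' emulate the statistical structure of a symbiont/pathogen interactome
#' study at one tenth scale: a 1200-protein host interactome standing in
#' for a ~12k screening space with a nested 800-protein subspace, 33
#' interacting effectors per organism averaging ~6.3 targets each (about
#' 207 interactions), 106 effector candidates screened against five
#' hormone reporters in duplicate, and ~31% of effector x reporter
#' combinations carrying a true multiplicative effect.
#'
#' @param seed integer seed; every generator is fully deterministic given
#'   the config.
#' @param nHost number of host proteins in the reference interactome.
#' @param interactomeModel `"erdos_renyi"` or `"configuration"`
#'   (geometric degree sequence).
#' @param meanDegree mean host-host degree.
#' @param organisms character vector of organism tags; the first is the
#'   focal symbiont.
#' @param effectorsPerOrganism interacting effectors per organism.
#' @param edgesPerEffectorMean mean of the shifted-geometric per-effector
#'   degree distribution (support 1, 2, ...).
#' @param rho convergence parameter: probability an edge reuses an
#'   already-targeted host protein of the same organism (planted
#'   intraspecies convergence; 0 = null).
#' @param sigma cross-organism sharing: probability an edge draws from the
#'   union of previously generated organisms' target pools (planted
#'   interspecies convergence; 0 = null).
#' @param subspaceFraction fraction of hosts forming the nested subspace.
#' @param hormoneCoverage per-hormone probability that a host protein
#'   carries that annotation label.
#' @param nTerms,termSizeRange annotation-term map shape.
#' @param screenEffectors effector candidates entering the reporter
#'   screen.
#' @param modulatorFraction fraction of effector x reporter combinations
#'   with a true effect.
#' @param effectFold fold-change of a true effect, applied
#'   multiplicatively to both conditions (direction random).
#' @param wellCV coefficient of variation of the multiplicative log-normal
#'   well noise.
#' @param replicates technical replicate wells per condition.
#' @param evReplicates empty-vector control wells per condition (controls
#'   are replicated more heavily than effector constructs so the baseline
#'   survives well-level QC).
#' @param lowGusFraction fraction of wells given a failed-transformation
#'   (low GUS) efficiency, targets for the QC filter.
#' @param treatmentInduction fold-induction of the reporter by the hormone
#'   treatment itself.
#' @param plateSize wells per plate.
#' @param mockMean,mockSd mock trait distribution for phenotyping (e.g.
#'   root length in mm).
#' @param controlResponse control lines' treated/mock response fraction.
#' @param nPlants plants per line and condition.
#' @return a list of class `"SimConfig"`.
#' @export
simConfig <- function(seed,
                      nHost = 1200L,
                      interactomeModel = c("erdos_renyi", "configuration"),
                      meanDegree = 4,
                      organisms = c("Si", "Rps", "Xcc", "Gor"),
                      effectorsPerOrganism = 33L,
                      edgesPerEffectorMean = 6.3,
                      rho = 0, sigma = 0,
                      subspaceFraction = 2 / 3,
                      hormoneCoverage = 0.04,
                      nTerms = 50L, termSizeRange = c(5L, 60L),
                      screenEffectors = 106L,
                      modulatorFraction = 0.31,
                      effectFold = 2.5,
                      wellCV = 0.2,
                      replicates = 2L,
                      evReplicates = 8L,
                      lowGusFraction = 0.05,
                      treatmentInduction = 5,
                      plateSize = 96L,
                      mockMean = 50, mockSd = 5,
                      controlResponse = 0.5,
                      nPlants = 30L) {
  stopifnot(rho >= 0, rho <= 1, sigma >= 0, sigma <= 1, rho + sigma <= 1,
            hormoneCoverage >= 0, hormoneCoverage <= 1)
  structure(list(
    seed = as.integer(seed), nHost = as.integer(nHost),
    interactomeModel = match.arg(interactomeModel),
    meanDegree = meanDegree, organisms = organisms,
    effectorsPerOrganism = as.integer(effectorsPerOrganism),
    edgesPerEffectorMean = edgesPerEffectorMean,
    rho = rho, sigma = sigma, subspaceFraction = subspaceFraction,
    hormoneCoverage = hormoneCoverage, nTerms = as.integer(nTerms),
    termSizeRange = as.integer(termSizeRange),
    screenEffectors = as.integer(screenEffectors),
    modulatorFraction = modulatorFraction, effectFold = effectFold,
    wellCV = wellCV, replicates = as.integer(replicates),
    evReplicates = as.integer(evReplicates),
    lowGusFraction = lowGusFraction,
    treatmentInduction = treatmentInduction,
    plateSize = as.integer(plateSize),
    mockMean = mockMean, mockSd = mockSd,
    controlResponse = controlResponse, nPlants = as.integer(nPlants)),
    class = "SimConfig")
}

hostIds <- function(n) {
  chr <- ((seq_len(n) - 1L) %% 5L) + 1L
  sprintf("AT%dG%05d", chr, 10L * seq_len(n))
}

#' Generate a synthetic reference host interactome
#'
#' Erdos-Renyi (fixed edge count `round(nHost * meanDegree / 2)`) or
#' configuration-model (geometric degree sequence) host-host network with
#' deterministic locus-style node ids, no self-loops, no multi-edges.
#'
#' @param cfg a [simConfig()].
#' @return a [ReferenceInteractome-class].
#' @export
genReferenceInteractome <- function(cfg) {
  stopifnot(cfg$nHost >= 2L)
  set.seed(cfg$seed)
  ids <- hostIds(cfg$nHost)
  m <- round(cfg$nHost * cfg$meanDegree / 2)
  if (m == 0)
    return(new("ReferenceInteractome",
               edges = data.frame(a = character(), b = character(),
                                  stringsAsFactors = FALSE),
               nodes = sort(ids), selfLoops = FALSE))
  g <- if (cfg$interactomeModel == "erdos_renyi")
    igraph::sample_gnm(cfg$nHost, m)
  else {
    deg <- 1L + stats::rgeom(cfg$nHost, 1 / cfg$meanDegree)
    if (sum(deg) %% 2L == 1L) deg[1L] <- deg[1L] + 1L
    igraph::sample_degseq(deg, method = "fast.heur.simple")
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  referenceInteractome(data.frame(a = ids[el[, 1L]], b = ids[el[, 2L]],
                                  stringsAsFactors = FALSE))
}

#' Generate nested search spaces over the synthetic hosts
#'
#' @param cfg a [simConfig()].
#' @return list with `full` (all hosts) and `sub` (the nested
#'   `subspaceFraction` subspace, verified subset of `full`).
#' @export
genSearchSpaces <- function(cfg) {
  ids <- hostIds(cfg$nHost)
  full <- searchSpace("full_space", ids)
  sub <- searchSpace("sub_space",
                     ids[seq_len(round(cfg$subspaceFraction * cfg$nHost))],
                     subsetOf = full)
  list(full = full, sub = sub)
}

#' Generate effector-host networks with planted convergence and sharing
#'
#' For each organism, each effector draws its degree from a shifted
#' geometric distribution; each edge's target is chosen as: with
#' probability `rho` uniformly from the organism's already-used targets
#' (planted intraspecies convergence, falling back to a fresh draw while
#' none exist), with probability `sigma` from the union of previously
#' generated organisms' target pools (planted cross-organism sharing),
#' otherwise uniformly from the organism's search space. With
#' `rho = sigma = 0` targets are i.i.d. uniform over the space — exactly
#' the null model of the resampling tests. Duplicate effector-target
#' pairs arising from reuse are collapsed.
#'
#' @param cfg a [simConfig()].
#' @param spaces named list: organism -> [SearchSpace-class] (or a single
#'   space used for all). Defaults to the full space of
#'   [genSearchSpaces()].
#' @return list with `networks` (named list of
#'   [EffectorHostNetwork-class]) and `truth` (the planted `rho`, `sigma`
#'   and per-organism edge counts before deduplication).
#' @export
genEffectorNetworks <- function(cfg, spaces = NULL) {
  if (is.null(spaces)) spaces <- genSearchSpaces(cfg)$full
  if (is(spaces, "SearchSpace"))
    spaces <- stats::setNames(rep(list(spaces), length(cfg$organisms)),
                              cfg$organisms)
  set.seed(cfg$seed + 1L)
  nets <- list()
  usedByOrg <- list()
  rawEdges <- integer()
  for (org in cfg$organisms) {
    members <- spaceMembers(spaces[[org]])
    if (length(members) == 0L) stop("empty search space for ", org)
    otherPool <- unique(unlist(usedByOrg, use.names = FALSE))
    effIds <- sprintf("%sE%02d", org, seq_len(cfg$effectorsPerOrganism))
    deg <- 1L + stats::rgeom(cfg$effectorsPerOrganism,
                             1 / cfg$edgesPerEffectorMean)
    total <- sum(deg)
    eff <- rep(effIds, deg)
    tgt <- character(total)
    ## tgt[seq_len(i - 1)] doubles as the organism's already-used pool
    for (i in seq_len(total)) {
      u <- stats::runif(1L)
      tgt[i] <- if (u < cfg$rho && i > 1L)
        tgt[sample.int(i - 1L, 1L)]
      else if (u < cfg$rho + cfg$sigma && length(otherPool))
        otherPool[sample.int(length(otherPool), 1L)]
      else
        members[sample.int(length(members), 1L)]
    }
    rawEdges[org] <- total
    nets[[org]] <- effectorHostNetwork(
      data.frame(effector = eff, target = tgt, stringsAsFactors = FALSE),
      organism = org, space = spaces[[org]])
    usedByOrg[[org]] <- unique(tgt)
  }
  list(networks = nets,
       truth = list(rho = cfg$rho, sigma = cfg$sigma,
                    rawEdgeCounts = rawEdges))
}

#' Generate hormone annotations and a term map for synthetic hosts
#'
#' Each hormone label is assigned to each node independently with
#' probability `hormoneCoverage`; terms get sizes uniform over
#' `termSizeRange` with members sampled without replacement.
#'
#' @param cfg a [simConfig()].
#' @param nodes character vector of host proteins.
#' @return list with `hormones` ([HormoneAnnotation-class]) and `terms`
#'   ([AnnotationMap-class]).
#' @export
genAnnotations <- function(cfg, nodes) {
  set.seed(cfg$seed + 2L)
  rows <- lapply(HORMONE_LABELS, function(h) {
    hit <- stats::runif(length(nodes)) < cfg$hormoneCoverage
    if (!any(hit)) return(NULL)
    data.frame(protein = nodes[hit], hormone = h, source = "database",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(protein = character(), hormone = character(),
                      source = character(), stringsAsFactors = FALSE)
  termRows <- lapply(seq_len(cfg$nTerms), function(i) {
    sz <- sample(seq(cfg$termSizeRange[1L],
                     min(cfg$termSizeRange[2L], length(nodes))), 1L)
    data.frame(gene = sample(nodes, sz),
               term = sprintf("TERM:%04d", i), stringsAsFactors = FALSE)
  })
  list(hormones = hormoneAnnotation(tab),
       terms = annotationMap(do.call(rbind, termRows)))
}

#' Generate reporter-screen plate data with planted effects
#'
#' Emulates a dual-reporter protoplast screen: per reporter hormone, wells
#' for the empty vector and every effector in both conditions and
#' `replicates` technical replicates, laid out on plates of `plateSize`
#' wells. A fraction `modulatorFraction` of effector x reporter
#' combinations are true modulators and multiply the luciferase signal by
#' `effectFold` (or its inverse) in both conditions. Each well has a
#' log-normal transformation efficiency shared multiplicatively by both
#' reporters, log-normal well noise of coefficient of variation `wellCV`
#' on each channel, and with probability `lowGusFraction` a collapsed
#' efficiency (QC target). The hormone treatment itself induces the
#' reporter `treatmentInduction`-fold.
#'
#' @param cfg a [simConfig()].
#' @param effectors character vector of effector ids; defaults to
#'   `cfg$screenEffectors` synthetic ids.
#' @return list with `wells` (data.frame as consumed by
#'   [qcFilterWells()]) and `truth` (data.frame `effector`, `reporter`,
#'   `modulator`, `direction`, `fold`).
#' @export
genScreenData <- function(cfg, effectors = NULL) {
  if (is.null(effectors))
    effectors <- sprintf("SIEC%03d", seq_len(cfg$screenEffectors))
  set.seed(cfg$seed + 3L)
  ## total per-channel CV = wellCV, split evenly (on the log scale)
  ## between the shared transformation efficiency and channel noise
  sdlog <- sqrt(log(1 + cfg$wellCV^2) / 2)
  lucBase <- 500; gusBase <- 1000
  truth <- expand.grid(effector = effectors, reporter = SCREEN_HORMONES,
                       stringsAsFactors = FALSE)
  truth$modulator <- stats::runif(nrow(truth)) < cfg$modulatorFraction
  truth$direction <- ifelse(stats::runif(nrow(truth)) < 0.5, 1L, -1L)
  truth$direction[!truth$modulator] <- 0L
  truth$fold <- cfg$effectFold^truth$direction
  truth$fold[!truth$modulator] <- 1

  wellList <- lapply(SCREEN_HORMONES, function(rep_) {
    gridEff <- expand.grid(construct = effectors,
                           condition = c("mock", "treated"),
                           replicate = seq_len(cfg$replicates),
                           stringsAsFactors = FALSE)
    gridEv <- expand.grid(construct = "EV",
                          condition = c("mock", "treated"),
                          replicate = seq_len(cfg$evReplicates),
                          stringsAsFactors = FALSE)
    grid <- rbind(gridEv, gridEff)
    grid$reporter <- rep_
    key <- match(paste(grid$construct, rep_),
                 paste(truth$effector, truth$reporter))
    fold <- ifelse(is.na(key), 1, truth$fold[key])
    ## transformation efficiency; a lowGus well gets a collapsed one
    eff <- stats::rlnorm(nrow(grid), 0, sdlog)
    low <- stats::runif(nrow(grid)) < cfg$lowGusFraction
    eff[low] <- eff[low] * 0.15
    induction <- ifelse(grid$condition == "treated",
                        cfg$treatmentInduction, 1)
    grid$luc <- lucBase * induction * fold * eff *
      stats::rlnorm(nrow(grid), 0, sdlog)
    grid$gus <- gusBase * eff * stats::rlnorm(nrow(grid), 0, sdlog)
    grid$plate <- sprintf("%s_p%02d", rep_,
                          ((seq_len(nrow(grid)) - 1L) %/% cfg$plateSize) + 1L)
    grid$well <- sprintf("w%03d",
                         ((seq_len(nrow(grid)) - 1L) %% cfg$plateSize) + 1L)
    grid
  })
  wells <- do.call(rbind, wellList)
  wells <- wells[, c("plate", "well", "construct", "reporter",
                     "condition", "luc", "gus")]
  rownames(wells) <- NULL
  list(wells = wells, truth = truth)
}

#' Generate whole-plant phenotyping data with planted tolerance
#'
#' Mock trait values are Normal(`mockMean`, `mockSd`); treated values are
#' Normal(`mockMean * response`, `mockSd`), where control lines share
#' `controlResponse` and each test line's response encodes its planted
#' tolerance: `response = controlResponse * (100 + tolerance) / 100`.
#'
#' @param cfg a [simConfig()].
#' @param lines data.frame with columns `line`, `genotype_class`,
#'   `plantedTolerance` (0 for control lines).
#' @param trait trait name (default `"primary_root_length"`).
#' @param treatment treatment label (default `"ABA"`).
#' @return list with `measurements` (as consumed by
#'   [hormoneTolerance()]) and `truth` (the `lines` table with the
#'   realised response fractions).
#' @export
genPhenotypingData <- function(cfg, lines,
                               trait = "primary_root_length",
                               treatment = "ABA") {
  stopifnot(all(c("line", "genotype_class", "plantedTolerance") %in%
                  names(lines)))
  set.seed(cfg$seed + 4L)
  lines$response <- cfg$controlResponse *
    (100 + lines$plantedTolerance) / 100
  rows <- lapply(seq_len(nrow(lines)), function(i) {
    mock <- stats::rnorm(cfg$nPlants, cfg$mockMean, cfg$mockSd)
    trt <- stats::rnorm(cfg$nPlants, cfg$mockMean * lines$response[i],
                        cfg$mockSd)
    data.frame(line = lines$line[i],
               genotype_class = lines$genotype_class[i],
               treatment = rep(c("mock", treatment), each = cfg$nPlants),
               replicate = rep(seq_len(cfg$nPlants), 2L),
               trait = trait, value = pmax(c(mock, trt), 0),
               stringsAsFactors = FALSE)
  })
  list(measurements = do.call(rbind, rows), truth = lines)
}
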