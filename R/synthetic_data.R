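# Synthetic study generator with a planted key regulator. Emulates the
# 3-cell-line x 2-evidence x 3-replicate design: a regulator node wired to
# a downstream cascade, differential genes drawn from the cascade, a
# binding motif planted in their promoters, log-ratio expression matrices,
# and binomial peptide-count tables.

#' Simulation configuration
#'
#' Defaults describe a study of 3 cell lines with 3 biological replicates
#' per population, a 300-gene universe, a planted regulator wired to a
#' fan-out-4 / depth-2 cascade (20 downstream genes), 15 planted
#' differential genes per cell line and evidence type, a log2 effect of
#' 2.0 over noise sd 0.2 on the transcript side, a 3-fold abundance shift
#' on the protein side, and a 10-matrix motif library whose planted motif
#' (12 bases, consensus probability 0.99) occurs in 80% of differential
#' promoters and 5% of background promoters.
#'
#' @param seed RNG seed for the whole study.
#' @param n_lines,n_reps Cell lines and replicates per population.
#' @param n_genes Gene universe size.
#' @param n_bg_edges Random background edges in the network.
#' @param fanout,depth Planted cascade fan-out and depth (depth must not
#'   exceed the master-regulator search radius of 10).
#' @param n_de Planted differential genes per line and evidence type.
#' @param effect,noise_sd Transcript log2 shift and replicate noise sd.
#' @param protein_fold Protein abundance fold for planted proteins.
#' @param detect_rate Baseline per-peptide detection probability scale.
#' @param abundance_sd Log-scale sd of per-protein baseline abundance.
#' @param n_motifs,motif_len Motif library size and motif length.
#' @param motif_sharpness Consensus-base probability of planted and decoy
#'   motifs.
#' @param plant_prob,bg_plant_prob Motif planting probability in
#'   differential vs background promoters.
#' @param mut_prob Per-base mutation probability of planted motif copies.
#' @param promoter_len Promoter window length (default 1101 = -1000..+100).
#' @param gc Background GC content (default 0.5, i.e. uniform).
#' @return A validated `kr_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_lines = 3L, n_reps = 3L,
                       n_genes = 300L, n_bg_edges = 600L,
                       fanout = 4L, depth = 2L, n_de = 15L,
                       effect = 2.0, noise_sd = 0.2,
                       protein_fold = 3.0, detect_rate = 0.45,
                       abundance_sd = 0.25,
                       n_motifs = 10L, motif_len = 12L,
                       motif_sharpness = 0.99,
                       plant_prob = 0.8, bg_plant_prob = 0.05,
                       mut_prob = 0.05, promoter_len = 1101L, gc = 0.5) {
  cfg <- list(seed = as.integer(seed), n_lines = as.integer(n_lines),
              n_reps = as.integer(n_reps), n_genes = as.integer(n_genes),
              n_bg_edges = as.integer(n_bg_edges),
              fanout = as.integer(fanout), depth = as.integer(depth),
              n_de = as.integer(n_de), effect = effect,
              noise_sd = noise_sd, protein_fold = protein_fold,
              detect_rate = detect_rate, abundance_sd = abundance_sd,
              n_motifs = as.integer(n_motifs),
              motif_len = as.integer(motif_len),
              motif_sharpness = motif_sharpness,
              plant_prob = plant_prob, bg_plant_prob = bg_plant_prob,
              mut_prob = mut_prob, promoter_len = as.integer(promoter_len),
              gc = gc)
  counts <- c(cfg$n_lines, cfg$n_reps, cfg$n_genes, cfg$fanout, cfg$depth,
              cfg$n_de, cfg$n_motifs, cfg$motif_len, cfg$promoter_len)
  if (any(counts <= 0)) stop("all counts must be positive")
  probs <- c(cfg$plant_prob, cfg$bg_plant_prob, cfg$mut_prob, cfg$gc,
             cfg$motif_sharpness)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$depth > 10L) stop("cascade depth exceeds the search radius (10)")
  if (cfg$noise_sd <= 0 || cfg$detect_rate <= 0) {
    stop("noise sd and detection rate must be positive")
  }
  if (cfg$n_de > cascade_size(cfg)) {
    stop("more planted differential genes than cascade nodes")
  }
  class(cfg) <- "kr_sim_config"
  cfg
}

cascade_size <- function(config) {
  sum(config$fanout^seq_len(config$depth))
}

gene_universe <- function(config) sprintf("G%04d", seq_len(config$n_genes))

#' Simulate the regulatory network with a planted cascade
#'
#' Wires a planted regulator to a tree of configured fan-out and depth
#' over designated gene nodes, then adds random background edges between
#' genes (no self-loops). Nodes are gene identifiers; every node is
#' gene-mapped.
#'
#' @param config A `kr_sim_config`.
#' @return List: `network` (`kr_network`) and `truth` fragment with
#'   `regulator`, `cascade` (downstream gene set), and `cascade_depth`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "kr_sim_config"))
  genes <- gene_universe(config)
  csize <- cascade_size(config)
  if (csize + 1L > config$n_genes) {
    stop("cascade larger than the gene universe")
  }
  set.seed(child_seed(config$seed, 1L))
  regulator <- genes[1L]
  cascade <- sample(genes[-1L], csize)
  from <- character(0); to <- character(0)
  level_nodes <- regulator
  used <- 0L
  for (d in seq_len(config$depth)) {
    next_n <- config$fanout^d
    nxt <- cascade[used + seq_len(next_n)]
    used <- used + next_n
    from <- c(from, rep(level_nodes, each = config$fanout))
    to <- c(to, nxt)
    level_nodes <- nxt
  }
  # background edges: uniform random ordered pairs, self-pairs discarded
  bf <- sample(genes, config$n_bg_edges, replace = TRUE)
  bt <- sample(genes, config$n_bg_edges, replace = TRUE)
  ok <- bf != bt
  edges <- data.frame(from = c(from, bf[ok]), to = c(to, bt[ok]),
                      stringsAsFactors = FALSE)
  net <- suppressWarnings(regulatory_network(edges, nodes = genes))
  list(network = net,
       truth = list(regulator = regulator, cascade = cascade,
                    cascade_depth = config$depth))
}

# per-line, per-evidence planted differential gene sets (from the cascade)
simulate_truth_sets <- function(config, truth) {
  set.seed(child_seed(config$seed, 2L))
  lines <- sprintf("line%d", seq_len(config$n_lines))
  truth$de_genes <- lapply(stats::setNames(lines, lines), function(ln) {
    list(transcript = sample(truth$cascade, config$n_de),
         protein = sample(truth$cascade, config$n_de))
  })
  truth$lines <- lines
  truth
}

random_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

sharp_pwm <- function(consensus, sharpness, id, tf) {
  L <- length(consensus)
  mat <- matrix((1 - sharpness) / 3, 4L, L, dimnames = list(DNA_BASES, NULL))
  mat[cbind(match(consensus, DNA_BASES), seq_len(L))] <- sharpness
  new_pwm(mat, id = id, tf = tf, pseudocount = 0.01)
}

#' Simulate promoters and the motif library
#'
#' Generates one promoter per gene (i.i.d. background composition) and a
#' motif library of one planted matrix (annotated with the planted
#' regulator as its TF) plus decoy matrices of the same construction
#' annotated with random other genes. Copies of the planted consensus,
#' mutated per base with probability `mut_prob`, are embedded at a random
#' offset and strand in differential-gene promoters with probability
#' `plant_prob` and in all other promoters with probability
#' `bg_plant_prob`.
#'
#' @param config A `kr_sim_config`.
#' @param truth Ground-truth list containing `regulator` and `de_genes`
#'   (see [simulate_study()]).
#' @return List: `promoters` (`kr_promoters`), `library`
#'   (`kr_pwm_library`, uncalibrated), and updated `truth` with
#'   `motif_id` and `consensus`.
#' @export
simulate_promoters <- function(config, truth) {
  stopifnot(inherits(config, "kr_sim_config"))
  if (config$motif_len > config$promoter_len) {
    stop("motif longer than the promoter window")
  }
  set.seed(child_seed(config$seed, 3L))
  genes <- gene_universe(config)
  de_union <- unique(norm_id(unlist(lapply(truth$de_genes, unlist))))

  consensus <- sample(DNA_BASES, config$motif_len, replace = TRUE)
  planted <- sharp_pwm(consensus, config$motif_sharpness, "M001",
                       truth$regulator)
  decoys <- lapply(seq_len(config$n_motifs - 1L), function(i) {
    sharp_pwm(sample(DNA_BASES, config$motif_len, replace = TRUE),
              config$motif_sharpness, sprintf("M%03d", i + 1L),
              sample(genes[-1L], 1L))
  })
  library <- pwm_library(c(list(planted), decoys))

  seqs <- vapply(genes, function(g) {
    s <- random_bases(config$promoter_len, config$gc)
    p_plant <- if (norm_id(g) %in% de_union) config$plant_prob else
      config$bg_plant_prob
    if (stats::runif(1) < p_plant) {
      copy <- consensus
      mut <- stats::runif(config$motif_len) < config$mut_prob
      if (any(mut)) {
        copy[mut] <- vapply(copy[mut], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
      }
      if (stats::runif(1) < 0.5) {
        copy <- rev(c(A = "T", C = "G", G = "C", T = "A")[copy])
      }
      at <- sample.int(config$promoter_len - config$motif_len + 1L, 1L)
      s[at:(at + config$motif_len - 1L)] <- copy
    }
    paste(s, collapse = "")
  }, character(1))

  truth$motif_id <- "M001"
  truth$consensus <- paste(consensus, collapse = "")
  list(promoters = promoter_set(seqs), library = library, truth = truth)
}

#' Simulate replicated log-ratio expression matrices
#'
#' Null genes are Normal(0, `noise_sd`) in both populations; the planted
#' transcript genes of each line are shifted by `effect` (log2) in the
#' high population.
#'
#' @param config A `kr_sim_config`.
#' @param truth Ground truth with per-line `de_genes`.
#' @return Named list per cell line of `list(high, low)` matrices.
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "kr_sim_config"))
  set.seed(child_seed(config$seed, 4L))
  genes <- gene_universe(config)
  lapply(stats::setNames(truth$lines, truth$lines), function(ln) {
    mk <- function() {
      matrix(stats::rnorm(config$n_genes * config$n_reps, 0, config$noise_sd),
             config$n_genes, config$n_reps,
             dimnames = list(genes, sprintf("rep%d", seq_len(config$n_reps))))
    }
    high <- mk(); low <- mk()
    planted <- truth$de_genes[[ln]]$transcript
    high[planted, ] <- high[planted, ] + config$effect
    list(high = high, low = low)
  })
}

#' Simulate peptide-count tables
#'
#' Observable peptide counts are drawn uniformly from 5..40 per protein.
#' Observed counts per replicate are binomial with detection probability
#' `min(0.95, detect_rate * abundance)`, where per-protein abundance is
#' log-normal with sd `abundance_sd` on the log scale; planted proteins
#' have their high-population abundance multiplied by `protein_fold`.
#'
#' @param config A `kr_sim_config`.
#' @param truth Ground truth with per-line `de_genes`.
#' @return Named list per cell line of `list(high, low)` `kr_peptides`.
#' @export
simulate_peptides <- function(config, truth) {
  stopifnot(inherits(config, "kr_sim_config"))
  set.seed(child_seed(config$seed, 5L))
  genes <- gene_universe(config)
  lapply(stats::setNames(truth$lines, truth$lines), function(ln) {
    observable <- sample(5:40, config$n_genes, replace = TRUE)
    abundance <- exp(stats::rnorm(config$n_genes, 0, config$abundance_sd))
    planted <- genes %in% truth$de_genes[[ln]]$protein
    ab_high <- abundance * ifelse(planted, config$protein_fold, 1)
    draw <- function(ab) {
      # detection saturates below 1 so replicate counts keep sampling noise
      p <- pmin(0.95, config$detect_rate * ab)
      obs <- vapply(seq_len(config$n_reps), function(r)
        stats::rbinom(config$n_genes, observable, p), numeric(config$n_genes))
      dimnames(obs) <- list(genes, sprintf("rep%d", seq_len(config$n_reps)))
      obs
    }
    list(high = peptide_table(draw(ab_high), observable, line = ln,
                              population = "high"),
         low = peptide_table(draw(abundance), observable, line = ln,
                             population = "low"))
  })
}

#' Simulate a complete study
#'
#' Assembles the full input bundle of the planted-regulator benchmark:
#' one regulatory network, one promoter set, one motif library, and per
#' cell line a pair of expression matrices and a pair of peptide tables,
#' all sharing the planted regulator's cascade as differential truth. The
#' bundle feeds [run_pipeline()] end to end. Everything is deterministic
#' given `config$seed`.
#'
#' @param config A `kr_sim_config` (default `sim_config()`).
#' @return List: `network`, `promoters`, `library`, `expression`,
#'   `peptides`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "kr_sim_config"))
  net <- simulate_network(config)
  truth <- simulate_truth_sets(config, net$truth)
  prom <- simulate_promoters(config, truth)
  truth <- prom$truth
  expr <- simulate_expression(config, truth)
  pept <- simulate_peptides(config, truth)
  list(network = net$network, promoters = prom$promoters,
       library = prom$library, expression = expr, peptides = pept,
       truth = truth, config = config)
}
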