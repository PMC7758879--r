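#' Specification for a synthetic genome with planted motifs
#'
#' Describes a toy genome of `n_genes` equal-length genes laid
#' head-to-tail on alternating strands, separated by intergenic spacers.
#' Promoter windows are filled i.i.d. from `base_composition`, and motif
#' instances are planted into them at Poisson rates that differ between a
#' designated target gene set and the background — the ground truth the
#' Monte Carlo enrichment test should recover. Spacers are at least as
#' long as the upstream window extent so promoter windows never collide,
#' and alternating strands exercise reverse-complement extraction by
#' construction.
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene length in bp; default 1000 (all genes pass the
#'   500 bp filter).
#' @param intergenic_length Spacer between genes in bp; must be at least
#'   `upstream`; default 200.
#' @param base_composition Probabilities of A, C, G, T; default uniform.
#' @param motifs List of [motif] objects to plant.
#' @param planting_rate_background Expected plants per promoter (per
#'   motif) outside the target set.
#' @param planting_rate_target Expected plants per promoter (per motif)
#'   inside the target set.
#' @param target_set_size Number of target genes (sampled uniformly).
#' @param upstream,downstream Promoter window extents the truth refers
#'   to; defaults 100/100.
#' @param seed Integer seed; the generated bundle is a deterministic
#'   function of the spec.
#' @return An object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_genes, gene_length = 1000,
                                  intergenic_length = 200,
                                  base_composition = rep(0.25, 4),
                                  motifs = list(),
                                  planting_rate_background = 0,
                                  planting_rate_target = 0,
                                  target_set_size = 0,
                                  upstream = 100, downstream = 100,
                                  seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (gene_length <= downstream) {
    stop("gene_length must exceed the downstream window extent")
  }
  if (intergenic_length < upstream) {
    stop("intergenic_length must be >= upstream so promoter windows ",
         "stay within spacers")
  }
  if (abs(sum(base_composition) - 1) > 1e-9 || any(base_composition < 0)) {
    stop("base_composition must be 4 probabilities summing to 1")
  }
  if (planting_rate_background < 0 || planting_rate_target < 0) {
    stop("planting rates must be >= 0")
  }
  if (target_set_size > n_genes) {
    stop("target_set_size exceeds n_genes")
  }
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 intergenic_length = as.integer(intergenic_length),
                 base_composition = base_composition, motifs = motifs,
                 planting_rate_background = planting_rate_background,
                 planting_rate_target = planting_rate_target,
                 target_set_size = as.integer(target_set_size),
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

# Draw one concrete instance word of a motif (consensus: uniform over each
# position's IUPAC set; PWM: per-position probabilities).
draw_motif_instance <- function(motif) {
  bases <- c("A", "C", "G", "T")
  if (motif$kind == "consensus") {
    mask <- iupac_mask(motif$consensus)
    paste(vapply(mask, function(m) {
      allowed <- bases[bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L]
      allowed[sample.int(length(allowed), 1)]
    }, character(1)), collapse = "")
  } else {
    paste(vapply(seq_len(motif$length), function(j) {
      sample(bases, 1, prob = motif$matrix[, j])
    }, character(1)), collapse = "")
  }
}

#' Generate a synthetic genome bundle with planted motifs
#'
#' Builds the genome sequence, gene annotation and ground truth described
#' by a [synthetic_genome_spec()]. For each gene and motif, a Poisson
#' number of instances (rate per the gene's target/background membership)
#' is planted at uniform non-overlapping offsets within the promoter
#' window, in transcription orientation (so plants on minus-strand genes
#' appear reverse-complemented on the plus strand of the contig). Every
#' plant is recorded in the truth manifest.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list of class `synthetic_bundle` with `genome`
#'   ([Biostrings::DNAStringSet], one contig `"chrS"`), `genes` (the
#'   annotation data.frame), `truth` (list: `target_set` [gene_set],
#'   `plants` data.frame, `expected_mean_target`,
#'   `expected_mean_background`) and the `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  withr::with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  n <- spec$n_genes
  gl <- spec$gene_length
  il <- spec$intergenic_length
  up <- spec$upstream
  dn <- spec$downstream
  bases <- c("A", "C", "G", "T")

  starts <- il + (seq_len(n) - 1L) * (gl + il) + 1L   # 1-based
  ends <- starts + gl - 1L
  strands <- rep(c("+", "-"), length.out = n)
  gene_ids <- sprintf("g%04d", seq_len(n))
  contig_len <- n * (gl + il) + il
  # contig held as UTF-8 codes for fast slice assignment of plants
  contig <- sample(utf8ToInt("ACGT"), contig_len, replace = TRUE,
                   prob = spec$base_composition)

  target <- sort(sample.int(n, spec$target_set_size))
  is_target <- seq_len(n) %in% target

  W <- up + dn
  plants <- list()
  for (i in seq_len(n)) {
    rate <- if (is_target[i]) spec$planting_rate_target else
      spec$planting_rate_background
    occupied <- integer(0)  # window positions already planted (any motif)
    for (motif in spec$motifs) {
      if (rate == 0) next
      k <- stats::rpois(1, rate)
      if (k == 0) next
      L <- motif$length
      placed <- 0L
      tries <- 0L
      while (placed < k) {
        tries <- tries + 1L
        if (tries > 200L) {
          stop("gene ", gene_ids[i], ": cannot place ", k,
               " non-overlapping plants of ", motif$name,
               " in a ", W, " bp window")
        }
        off <- sample.int(W - L + 1L, 1L) - 1L
        span <- off:(off + L - 1L)
        if (length(intersect(span, occupied)) > 0) next
        occupied <- c(occupied, span)
        word <- draw_motif_instance(motif)
        if (strands[i] == "+") {
          gstart <- (starts[i] - 1L - up) + off  # 0-based genomic
          contig[(gstart + 1L):(gstart + L)] <- utf8ToInt(word)
        } else {
          gstart <- ends[i] + up - off - L       # 0-based genomic
          contig[(gstart + 1L):(gstart + L)] <-
            utf8ToInt(revcomp_dna(word))
        }
        plants[[length(plants) + 1L]] <- data.frame(
          gene_id = gene_ids[i], motif = motif$name, offset = off,
          strand = "+", word = word, stringsAsFactors = FALSE)
        placed <- placed + 1L
      }
    }
  }
  plants <- if (length(plants) > 0) {
    do.call(rbind, plants)
  } else {
    data.frame(gene_id = character(), motif = character(),
               offset = integer(), strand = character(),
               word = character(), stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(
    stats::setNames(intToUtf8(contig), "chrS"))
  genes <- data.frame(gene_id = gene_ids, contig = "chrS",
                      strand = strands, start = starts, end = ends,
                      length = ends - starts + 1L,
                      stringsAsFactors = FALSE)
  truth <- list(
    target_set = if (length(target) > 0) {
      gene_set("target", gene_ids[target])
    },
    plants = plants,
    # expected planted occurrences per promoter, per motif
    expected_mean_target = spec$planting_rate_target,
    expected_mean_background = spec$planting_rate_background
  )
  structure(list(genome = genome, genes = genes, truth = truth,
                 spec = spec),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to standard files
#'
#' Emits FASTA (genome), GFF3 (genes), a target gene-set list, and the
#' truth manifest as tab-separated text, in the same dialects the
#' package's readers consume.
#'
#' @param bundle A `synthetic_bundle` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "genes.gff3"),
             target_set = file.path(dir, "target_genes.txt"),
             truth = file.path(dir, "truth_plants.tsv"))
  Biostrings::writeXStringSet(bundle$genome, paths["genome"])
  g <- bundle$genes
  gff <- c("##gff-version 3",
           paste(g$contig, "motifmc_sim", "gene", g$start, g$end, ".",
                 g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"))
  writeLines(gff, paths["annotation"])
  writeLines(c("# synthetic target gene set",
               bundle$truth$target_set$gene_ids), paths["target_set"])
  utils::write.table(bundle$truth$plants, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Specification for synthetic behavioral assays
#'
#' @param n_worms Worms at assay start; default 20.
#' @param per_minute_leaving_prob Per-minute, per-worm leaving hazard.
#' @param duration Observation window in minutes; default 15.
#' @param grid_shape `c(rows, cols)` of the exploration plate grid;
#'   default 21 x 21.
#' @param walk_steps Number of random-walk steps for track simulation.
#' @param step_kernel 3 x 3 probability matrix over moves (centre entry =
#'   probability of staying put); default uniform over the 8 neighbours.
#' @param seed Integer seed.
#' @return An object of class `synthetic_behavior_spec`.
#' @export
synthetic_behavior_spec <- function(n_worms = 20,
                                    per_minute_leaving_prob = 0.05,
                                    duration = 15,
                                    grid_shape = c(21, 21),
                                    walk_steps = 200,
                                    step_kernel = NULL,
                                    seed = 1L) {
  if (per_minute_leaving_prob < 0 || per_minute_leaving_prob > 1) {
    stop("per_minute_leaving_prob must be in [0, 1]")
  }
  if (is.null(step_kernel)) {
    step_kernel <- matrix(1 / 8, 3, 3)
    step_kernel[2, 2] <- 0
  }
  step_kernel <- as.matrix(step_kernel)
  if (!all(dim(step_kernel) == c(3, 3)) || any(step_kernel < 0) ||
      abs(sum(step_kernel) - 1) > 1e-9) {
    stop("step_kernel must be a 3x3 probability matrix summing to 1")
  }
  structure(list(n_worms = as.integer(n_worms),
                 per_minute_leaving_prob = per_minute_leaving_prob,
                 duration = as.integer(duration),
                 grid_shape = as.integer(grid_shape),
                 walk_steps = as.integer(walk_steps),
                 step_kernel = step_kernel, seed = as.integer(seed)),
            class = "synthetic_behavior_spec")
}

#' Simulate a food-leaving event log
#'
#' Each worm remaining on the patch leaves in each minute independently
#' with the spec's per-minute hazard; leaving is absorbing.
#'
#' @param spec A [synthetic_behavior_spec()].
#' @return A [leaving_log()].
#' @export
generate_leaving_log <- function(spec) {
  stopifnot(inherits(spec, "synthetic_behavior_spec"))
  withr::with_seed(spec$seed, {
    remaining <- spec$n_worms
    leavers <- integer(spec$duration)
    for (m in seq_len(spec$duration)) {
      leavers[m] <- stats::rbinom(1, remaining,
                                  spec$per_minute_leaving_prob)
      remaining <- remaining - leavers[m]
    }
    leaving_log(leavers, spec$n_worms)
  })
}

#' Simulate an exploration track
#'
#' Random walk on the plate grid starting from the patch centre; each
#' step moves to one of the 8 neighbours (or stays) per the step kernel,
#' and attempted moves off the plate leave the worm in place. Occupancy
#' records every visited square.
#'
#' @param spec A [synthetic_behavior_spec()].
#' @return An [exploration_grid()].
#' @export
generate_track <- function(spec) {
  stopifnot(inherits(spec, "synthetic_behavior_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$grid_shape[1]
    nc <- spec$grid_shape[2]
    occ <- matrix(FALSE, nr, nc)
    pos <- ceiling(c(nr, nc) / 2)
    occ[pos[1], pos[2]] <- TRUE
    moves <- cbind(dx = rep(-1:1, times = 3), dy = rep(-1:1, each = 3))
    probs <- as.vector(spec$step_kernel)
    if (spec$walk_steps > 0) {
      picks <- sample.int(9, spec$walk_steps, replace = TRUE, prob = probs)
      for (s in seq_len(spec$walk_steps)) {
        cand <- pos + moves[picks[s], ]
        if (cand[1] >= 1 && cand[1] <= nr && cand[2] >= 1 &&
              cand[2] <= nc) {
          pos <- cand
        }
        occ[pos[1], pos[2]] <- TRUE
      }
    }
    exploration_grid(occ, patch_center = ceiling(c(nr, nc) / 2))
  })
}
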