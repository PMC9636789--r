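# Synthetic-data generators. Every input the toolkit consumes can be produced
# here under a known ground-truth cleavage law, so downstream fits can be
# scored against planted parameters.

KERNEL_OFFSETS <- 7:57  # cleavage mass support relative to CSE start

#' Default ground-truth cleavage law
#'
#' The default law plants an AATAAA-consensus CSE weight matrix (ATTAAA as a
#' strong alternative at position 2), an upstream CFIm-like TGTA enhancer, a
#' downstream T-rich enhancer and a G-run silencer, with a Gaussian-shaped
#' cleavage kernel peaking ~21 nt downstream of the CSE start. The distal
#' baseline is placed so that proximal proportions of random library members
#' spread over most of (0, 1).
#'
#' @param noise_dispersion Dirichlet-multinomial dispersion (default 0 =
#'   multinomial counts).
#' @return a \linkS4class{GroundTruthLaw}.
#' @export
defaultLaw <- function(noise_dispersion = 0) {
  pwm <- matrix(0, 4L, 6L, dimnames = list(DNA_BASES, NULL))
  consensus <- c("A", "A", "T", "A", "A", "A")
  for (i in 1:6) pwm[consensus[i], i] <- 1.2
  pwm["T", 2L] <- 0.8  # ATTAAA variant
  kern <- exp(-0.5 * ((KERNEL_OFFSETS - 21) / 6)^2)
  new("GroundTruthLaw",
      cse_pwm = pwm,
      motif_effects = list(
        list(motif = "TGTA", window = c(10L, 62L), effect = 0.6),
        list(motif = "TTTT", window = c(76L, 140L), effect = 0.8),
        list(motif = "GGGG", window = c(0L, 204L), effect = -0.5)
      ),
      cleavage_kernel = kern / sum(kern),
      distal_baseline_logit = 6.5,
      noise_dispersion = noise_dispersion)
}

#' Strength logit of a sequence under a ground-truth law
#'
#' The analytic oracle used throughout the tests: strength is the sum of the
#' CSE weight-matrix score at `cse_offset` plus all positional motif effects.
#' The law-implied proximal proportion is
#' `plogis(lawLogit(...) - law@distal_baseline_logit)`.
#'
#' @param law a \linkS4class{GroundTruthLaw}.
#' @param seq DNA string (any length >= cse_offset + 6).
#' @param cse_offset 0-based CSE start (default 69, the conventional 1-based
#'   position 70).
#' @return strength logit (scalar).
#' @export
lawLogit <- function(law, seq, cse_offset = 69L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  hex <- chars[(cse_offset + 1L):(cse_offset + 6L)]
  a <- sum(law@cse_pwm[cbind(match(hex, DNA_BASES), 1:6)])
  for (me in law@motif_effects) {
    hits <- motifHits(seq, me$motif)
    a <- a + me$effect * sum(hits >= me$window[1L] & hits <= me$window[2L])
  }
  a
}

#' Law-implied proximal isoform proportion
#' @inheritParams lawLogit
#' @return proportion in (0, 1).
#' @export
lawProximal <- function(law, seq, cse_offset = 69L) {
  sigmoid(lawLogit(law, seq, cse_offset) - law@distal_baseline_logit)
}

# Full 206-way target cleavage vector implied by the law.
lawTarget <- function(law, seq, cse_offset = 69L) {
  prox <- lawProximal(law, seq, cse_offset)
  y <- numeric(OUT_LEN)
  pos <- cse_offset + KERNEL_OFFSETS + 1L   # 1-based bin indices
  keep <- pos >= 1L & pos <= PAS_LEN
  kern <- law@cleavage_kernel[keep]
  kern <- kern / sum(kern)
  y[pos[keep]] <- prox * kern
  y[OUT_LEN] <- 1 - prox
  y
}

# Draw a CSE hexamer from the position-wise softmax of the law's weight matrix.
drawCSE <- function(law, temperature = 2) {
  probs <- apply(law@cse_pwm * temperature, 2L, softmax)
  paste(DNA_BASES[apply(probs, 2L, function(p) sample.int(4L, 1L, prob = p))],
        collapse = "")
}

#' Generate a synthetic PAS reporter library
#'
#' Draws `n` 205-nt reporter sequences with a CSE planted near 0-based offset
#' 69 (1-based position 70), computes each record's true 206-way cleavage
#' distribution under the law, and draws read counts at the stated depth.
#' Sequences with more than 75% adenine in any 12-20-bp window are rejected
#' and resampled (the internal-priming artifact filter).
#'
#' @param n number of records (>= 1).
#' @param law a \linkS4class{GroundTruthLaw}; default [defaultLaw()].
#' @param seed integer root seed; the operation draws from its own derived
#'   stream, so identical (arguments, seed) give byte-identical bundles.
#' @param depth reads per record (default 200).
#' @param cse_jitter maximum uniform jitter (nt) applied to the CSE offset
#'   (default 0: all records aligned at offset 69).
#' @return a \linkS4class{PASBundle}.
#' @export
generatePASLibrary <- function(n, law = defaultLaw(), seed = 1L, depth = 200L,
                               cse_jitter = 0L) {
  stopifnot(n >= 1, depth >= 1)
  validObject(law)
  if (any(law@cleavage_kernel < 0) || sum(law@cleavage_kernel) <= 0)
    stop("invalid law: cleavage kernel not normalizable")
  with_seed(deriveSeed(seed, "pas_library"), {
    seqs <- character(n)
    offs <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        off <- 69L + if (cse_jitter > 0L)
          sample.int(2L * cse_jitter + 1L, 1L) - cse_jitter - 1L else 0L
        s <- randomDNA(1L, PAS_LEN)
        s <- paste0(substr(s, 1L, off), drawCSE(law),
                    substr(s, off + 7L, PAS_LEN))
        if (!hasRichWindow(s)) break
      }
      seqs[i] <- s
      offs[i] <- off
    }
    targets <- vapply(seq_len(n),
                      function(i) lawTarget(law, seqs[i], offs[i]),
                      numeric(OUT_LEN))
    counts <- matrix(0L, OUT_LEN, n)
    for (i in seq_len(n)) {
      p <- targets[, i]
      if (law@noise_dispersion > 0) {
        alpha <- p / law@noise_dispersion
        g <- rgamma(OUT_LEN, shape = alpha)
        g[alpha == 0] <- 0
        p <- g / sum(g)
      }
      counts[, i] <- rmultinom(1L, depth, p)
    }
    bundle <- SummarizedExperiment(
      assays = SimpleList(counts = counts, target = targets),
      colData = DataFrame(
        sequence = seqs,
        library = sample.int(13L, n, replace = TRUE),
        cse_offset = offs,
        depth = rep(as.integer(depth), n)
      ),
      metadata = list(law = law, seed = as.integer(seed))
    )
    as(bundle, "PASBundle")
  })
}

# ---- Multi-PAS genes ---------------------------------------------------------

#' Default planted multi-PAS regression weights
#'
#' Weight set for the masked-softmax isoform model: one row of
#' (score, 4 stability PCs, log-distance, bias) weights per role (distal,
#' proximal). The proximal bias is fixed at 0: a shared shift of both role
#' biases cancels in the softmax, so only the bias difference is
#' identifiable.
#'
#' @return named list with `distal` and `proximal` numeric vectors (length 7,
#'   names score, saluki1..4, distance, bias).
#' @export
defaultMultiPASWeights <- function() {
  nm <- c("score", paste0("saluki", 1:4), "distance", "bias")
  list(distal = setNames(c(1.0, 0.30, -0.25, 0.30, -0.25, -0.40, 0.80), nm),
       proximal = setNames(c(0.80, 0.25, -0.25, 0.25, 0.25, -0.30, 0.00), nm))
}

# Role score f = w.score*logit + sum w.saluki*PCs + w.distance*d + w.bias
roleScore <- function(w, logit, saluki, d) {
  w["score"] * logit + drop(saluki %*% w[paste0("saluki", 1:4)]) +
    w["distance"] * d + w["bias"]
}

#' Generate synthetic multi-PAS genes
#'
#' Each gene receives 2-10 PASs with random per-PAS strength logits,
#' stability-embedding PCs with geometrically decaying variance (so the first
#' 4 PCs dominate), inter-PAS distances between 50 and 40,000 bp, and isoform
#' counts drawn from the masked-softmax law under the planted regression
#' weights (the distal-most PAS is scored with the distal role, all others
#' with the proximal role).
#'
#' @param n_genes number of genes.
#' @param weights planted weights as from [defaultMultiPASWeights()].
#' @param seed integer root seed.
#' @param depth mean total read count per gene (default 800).
#' @return a data.frame (one row per gene x PAS) with columns gene, pas,
#'   n_pas, is_distal, logit, saluki1..4, distance, count; the planted
#'   weights are attached as `attr(, "true_weights")`.
#' @export
generateMultiPASGenes <- function(n_genes, weights = defaultMultiPASWeights(),
                                  seed = 1L, depth = 800L) {
  stopifnot(all(is.finite(unlist(weights))))
  with_seed(deriveSeed(seed, "multi_pas_genes"), {
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      k <- sample(2:10, 1L)
      logits <- rnorm(k, 0, 1.5)
      saluki <- cbind(rnorm(k, 0, 2), rnorm(k, 0, 1.5),
                      rnorm(k, 0, 1), rnorm(k, 0, 0.75))
      gaps <- exp(runif(k - 1L, log(50), log(40000)))
      d <- log10(1 + c(0, cumsum(gaps)))
      f <- numeric(k)
      for (i in seq_len(k)) {
        role <- if (i == k) weights$distal else weights$proximal
        f[i] <- roleScore(role, logits[i], saluki[i, , drop = FALSE], d[i])
      }
      p <- softmax(f)
      cnt <- drop(rmultinom(1L, depth, p))
      rows[[g]] <- data.frame(
        gene = g, pas = seq_len(k), n_pas = k,
        is_distal = seq_len(k) == k, logit = logits,
        saluki1 = saluki[, 1L], saluki2 = saluki[, 2L],
        saluki3 = saluki[, 3L], saluki4 = saluki[, 4L],
        distance = d, count = cnt
      )
    }
    out <- do.call(rbind, rows)
    attr(out, "true_weights") <- weights
    out
  })
}

# ---- Paired-condition (tissue) dataset --------------------------------------

#' Generate a paired-condition APA dataset with a planted motif effect
#'
#' Builds multi-PAS genes whose PAS sequences are full 205-nt records under
#' the ground-truth law; baseline logits are the law's strength logits.
#' Condition A ("reference") proportions follow a masked softmax of the
#' baseline logits and log distances; in condition B ("tissue") every PAS
#' containing the planted motif receives an extra `effect` logits. Genes with
#' fewer than 10 reads in either condition are removed.
#'
#' @param n_genes number of genes.
#' @param motif planted condition-specific motif (default "TGTGTG", a
#'   GT-rich CstF-like element long enough that chance occurrences in a
#'   205-nt background are rare).
#' @param effect additive logit effect in condition B for motif-bearing PASs.
#' @param seed integer root seed.
#' @param law ground-truth law used for sequences and baseline logits.
#' @param depth per-gene read depth per condition (default 300).
#' @param max_pas maximum PASs per gene (default 6).
#' @return data.frame (gene x PAS rows): gene, pas, n_pas, sequence,
#'   cse_offset, logit_base, distance, has_motif, count_ref, count_tissue;
#'   planted effect in `attr(, "true_effect")`.
#' @export
generateTissueDataset <- function(n_genes, motif = "TGTGTG", effect = 2.0,
                                  seed = 1L, law = defaultLaw(), depth = 300L,
                                  max_pas = 6L) {
  stopifnot(is.finite(effect))
  with_seed(deriveSeed(seed, "tissue_dataset"), {
    w_dist <- -0.3
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      k <- sample(2:max_pas, 1L)
      seqs <- character(k)
      for (i in seq_len(k)) {
        repeat {
          s <- randomDNA(1L, PAS_LEN)
          s <- paste0(substr(s, 1L, 69L), drawCSE(law), substr(s, 76L, PAS_LEN))
          # plant the condition-specific motif in ~40% of PASs, downstream
          if (runif(1) < 0.4) {
            at <- sample(90:180, 1L)
            substr(s, at, at + nchar(motif) - 1L) <- motif
          }
          if (!hasRichWindow(s)) break
        }
        seqs[i] <- s
      }
      has_motif <- vapply(seqs, function(s) length(motifHits(s, motif)) > 0,
                          logical(1), USE.NAMES = FALSE)
      logit_base <- vapply(seqs, function(s) lawLogit(law, s) -
                             law@distal_baseline_logit, numeric(1),
                           USE.NAMES = FALSE)
      gaps <- exp(runif(k - 1L, log(50), log(40000)))
      d <- log10(1 + c(0, cumsum(gaps)))
      f_ref <- logit_base + w_dist * d
      f_tis <- f_ref + effect * has_motif
      cnt_ref <- drop(rmultinom(1L, depth, softmax(f_ref)))
      cnt_tis <- drop(rmultinom(1L, depth, softmax(f_tis)))
      rows[[g]] <- data.frame(
        gene = g, pas = seq_len(k), n_pas = k, sequence = seqs,
        cse_offset = 69L, logit_base = logit_base, distance = d,
        has_motif = has_motif, count_ref = cnt_ref, count_tissue = cnt_tis
      )
    }
    out <- do.call(rbind, rows)
    keep <- tapply(out$count_ref, out$gene, sum) >= 10 &
      tapply(out$count_tissue, out$gene, sum) >= 10
    out <- out[out$gene %in% as.integer(names(keep))[keep], ]
    rownames(out) <- NULL
    attr(out, "true_effect") <- effect
    attr(out, "motif") <- motif
    out
  })
}

# ---- Case/control variant cohort --------------------------------------------

#' Generate a case/control variant cohort with planted gain-of-function
#' enrichment
#'
#' Builds a background PAS catalog (each PAS carrying a weakened CSE so that
#' consensus-restoring SNVs are available as gain-of-function events) plus a
#' background variant catalog with allele frequencies spanning unobserved to
#' common, then draws case and control single-nucleotide variant sets in
#' which the case set carries `enrichment`-fold more gain-of-function
#' variants (law log odds ratio > ln 2) than the control set.
#'
#' @param n_case,n_ctrl cohort sizes.
#' @param enrichment fold enrichment of gain-of-function variants in cases
#'   (>= 1).
#' @param seed integer root seed.
#' @param law ground-truth law used to score variants.
#' @param n_pas number of background PASs (default 40).
#' @param base_gof_rate control-group gain-of-function rate (default 0.1).
#' @return list with elements `case`, `ctrl` (variant data.frames: pas, wt,
#'   var, offset, lor_true, gof), `pas` (PAS catalog: id, sequence,
#'   downstream_neighbor_nt), and `background` (catalog of observed variants
#'   with allele counts/frequencies and law LORs).
#' @export
generateVariantCohort <- function(n_case, n_ctrl, enrichment = 1, seed = 1L,
                                  law = defaultLaw(), n_pas = 40L,
                                  base_gof_rate = 0.1) {
  stopifnot(enrichment >= 1)
  with_seed(deriveSeed(seed, "variant_cohort"), {
    consensus <- c("A", "A", "T", "A", "A", "A")
    pas_seq <- character(n_pas)
    weak_pos <- integer(n_pas)
    for (p in seq_len(n_pas)) {
      repeat {
        s <- randomDNA(1L, PAS_LEN)
        hex <- consensus
        wp <- sample(1:6, 1L)
        hex[wp] <- sample(setdiff(c("C", "G"), hex[wp]), 1L)
        s <- paste0(substr(s, 1L, 69L), paste(hex, collapse = ""),
                    substr(s, 76L, PAS_LEN))
        if (!hasRichWindow(s)) break
      }
      pas_seq[p] <- s
      weak_pos[p] <- wp
    }
    neighbor_nt <- sample(c(sample(60:190, ceiling(n_pas / 4), replace = TRUE),
                            sample(250:5000, n_pas - ceiling(n_pas / 4),
                                   replace = TRUE)))
    gof_variant <- function(p) {
      # restore the weakened CSE position to consensus: strong positive LOR
      off <- 69L + weak_pos[p] - 1L
      list(offset = off, base = consensus[weak_pos[p]])
    }
    neutral_variant <- function(p) {
      repeat {
        off <- sample(c(5:60, 145:200), 1L)
        ref <- substr(pas_seq[p], off + 1L, off + 1L)
        b <- sample(setdiff(DNA_BASES, ref), 1L)
        v <- substituteBase(pas_seq[p], off, b)
        lor <- lawLogit(law, v) - lawLogit(law, pas_seq[p])
        if (abs(lor) <= log(2)) return(list(offset = off, base = b))
      }
    }
    draw_set <- function(n, gof_rate) {
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        p <- sample.int(n_pas, 1L)
        vv <- if (runif(1) < gof_rate) gof_variant(p) else neutral_variant(p)
        var <- substituteBase(pas_seq[p], vv$offset, vv$base)
        lor <- lawLogit(law, var) - lawLogit(law, pas_seq[p])
        rows[[i]] <- data.frame(pas = p, wt = pas_seq[p], var = var,
                                offset = vv$offset, lor_true = lor,
                                gof = lor > log(2))
      }
      do.call(rbind, rows)
    }
    q1 <- min(0.9, base_gof_rate * enrichment)
    case <- draw_set(n_case, q1)
    ctrl <- draw_set(n_ctrl, base_gof_rate)
    # background catalog: random observed variants with allele counts from a
    # heavy-tailed distribution (singletons through common, AN = 150000)
    bg_rows <- vector("list", n_pas)
    an <- 150000L
    for (p in seq_len(n_pas)) {
      m <- sample(10:25, 1L)
      offs <- sample(0:(PAS_LEN - 1L), m)
      entries <- lapply(offs, function(off) {
        ref <- substr(pas_seq[p], off + 1L, off + 1L)
        b <- sample(setdiff(DNA_BASES, ref), 1L)
        var <- substituteBase(pas_seq[p], off, b)
        ac <- ceiling(exp(rnorm(1L, 0, 2.5)))
        data.frame(pas = p, offset = off, ref = ref, alt = b,
                   allele_count = min(ac, an),
                   lor = lawLogit(law, var) - lawLogit(law, pas_seq[p]))
      })
      bg_rows[[p]] <- do.call(rbind, entries)
    }
    background <- do.call(rbind, bg_rows)
    background$allele_freq <- background$allele_count / an
    background$af_class <- cut(background$allele_count,
                               breaks = c(-Inf, 1, 10, 0.001 * an, Inf),
                               labels = c("singleton", "rare", "low_freq",
                                          "common"))
    list(case = case, ctrl = ctrl,
         pas = data.frame(id = seq_len(n_pas), sequence = pas_seq,
                          downstream_neighbor_nt = neighbor_nt),
         background = background)
  })
}

# ---- Paired reads ------------------------------------------------------------

#' Generate paired MPRA reads from a bundle
#'
#' For every record, draws cleavage sites from its true cleavage distribution
#' and emits read 1 (reference sequence up to the cleavage position followed
#' by a 25-nt poly(A) run; distal reads carry the full reference with no
#' poly(A)) and read 2 (the UMI). Substitution errors are injected at
#' `error_rate` per base. A truth table of (record, site, umi) is returned
#' alongside.
#'
#' @param bundle a \linkS4class{PASBundle}.
#' @param reads_per_record reads drawn per record (>= 1).
#' @param umi_len UMI length (default 8).
#' @param error_rate per-base substitution error probability (default 0).
#' @param seed integer root seed.
#' @param dir optional directory; if given, gzipped FASTQ files
#'   `reads_R1.fastq.gz` / `reads_R2.fastq.gz` are written there.
#' @return list with `read1`, `read2` (character vectors), `truth`
#'   (data.frame record, site [0-based poly(A) start offset, i.e. the number
#'   of templated reference bases; NA for distal], umi), and file paths when
#'   `dir` is given.
#' @export
generateReads <- function(bundle, reads_per_record, umi_len = 8L,
                          error_rate = 0, seed = 1L, dir = NULL) {
  stopifnot(reads_per_record >= 1)
  with_seed(deriveSeed(seed, "reads"), {
    seqs <- pasSequences(bundle)
    targets <- cleavageTargets(bundle)
    n <- ncol(targets)
    recs <- rep(seq_len(n), each = reads_per_record)
    sites <- integer(length(recs))
    r1 <- character(length(recs))
    umis <- randomDNA(length(recs), umi_len)
    inject <- function(s) {
      if (error_rate <= 0) return(s)
      ch <- strsplit(s, "")[[1]]
      hit <- which(runif(length(ch)) < error_rate)
      for (h in hit) ch[h] <- sample(setdiff(DNA_BASES, ch[h]), 1L)
      paste(ch, collapse = "")
    }
    k <- 1L
    for (i in seq_len(n)) {
      draw <- sample.int(OUT_LEN, reads_per_record, replace = TRUE,
                         prob = targets[, i])
      for (s in draw) {
        if (s == OUT_LEN) {
          sites[k] <- NA_integer_
          r1[k] <- inject(seqs[i])
        } else {
          # site = number of templated bases = 0-based poly(A) start offset,
          # recorded in its 5'-most equivalent representation: cleavage
          # immediately after templated adenosines is indistinguishable from
          # cleavage before them, so trailing A's are folded into the
          # poly(A) run
          prefix <- substr(seqs[i], 1L, s)
          trail <- nchar(prefix) - nchar(sub("A*$", "", prefix))
          sites[k] <- s - trail
          r1[k] <- inject(paste0(prefix, strrep("A", 25L)))
        }
        k <- k + 1L
      }
    }
    truth <- data.frame(record = recs, site = sites, umi = umis)
    out <- list(read1 = r1, read2 = umis, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      ids <- sprintf("read_%06d", seq_along(r1))
      p1 <- file.path(dir, "reads_R1.fastq.gz")
      p2 <- file.path(dir, "reads_R2.fastq.gz")
      writeFastqGz(ids, r1, p1)
      writeFastqGz(ids, umis, p2)
      out$r1_path <- p1
      out$r2_path <- p2
    }
    out
  })
}

# Plain FASTQ writer (constant quality); kept minimal as record fields are
# fully synthetic.
writeFastqGz <- function(ids, seqs, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(l) strrep("I", l),
                           character(1))), con)
  invisible(path)
}

#' Read a (possibly gzipped) FASTQ file's sequences
#' @param path FASTQ or FASTQ.GZ path.
#' @return named character vector of read sequences.
#' @export
readFastqSeqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}
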