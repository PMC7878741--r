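#' Specify a synthetic fixture
#'
#' Describes a complete toy input set -- gene annotation, repeat
#' annotation, TAPAS output and genome FASTA -- with planted ground truth
#' for every downstream stage. The generator stands in for the UCSC
#' macFas5 downloads and the unpublished 30-animal RNA-seq that the real
#' analysis consumed; defaults are desk-scale (2 chromosomes x 1 Mb, 20
#' genes) so the full pipeline runs in seconds.
#'
#' Planted genes are laid out on a non-overlapping grid with generous UTRs
#' (350-500 bp), so every positional category has room to be planted
#' unambiguously; planted repeat placement guarantees the truth label by
#' construction (e.g. a `UTR3_END` repeat is placed to span the terminal
#' base inside a 3'UTR block with margins that rule out any
#' higher-precedence category).
#'
#' @param seed Integer seed; one pseudo-random stream drives every
#'   placement decision, so a given spec is byte-reproducible.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_genes Number of genes.
#' @param exon_count_range Length-2 integer range of exons per gene.
#' @param utr3_length_range,utr5_length_range UTR lengths (bp); keep the
#'   lower bound at >= 350 so planted elements (<= 310 bp) fit with margins.
#' @param planted_repeats Data frame with columns `repName`, `category`
#'   (a [POSITIONAL_CATEGORIES] value), `orientation` (`SENSE`/`ANTISENSE`),
#'   `count`, and optionally `repClass`/`repFamily` (default SINE/Alu).
#' @param planted_apa Data frame with columns `region` (`POLY_A_TAIL`,
#'   `A_RICH_LINKER`, `LEFT_ARM`, `RIGHT_ARM` or `OFF_ELEMENT`) and
#'   `count`; sites are planted on genes carrying a sense `UTR3_END`
#'   element of `apa_target_rep_name`.
#' @param anatomy_cfg An [anatomy_config()].
#' @param accession_mix Fraction of genes given registered `NM_` accessions
#'   (the rest get predicted `XM_`).
#' @param apa_target_rep_name Subfamily whose elements receive planted APA
#'   sites.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed,
                         n_chromosomes = 2L, chrom_length = 1000000L,
                         n_genes = 20L,
                         exon_count_range = c(1L, 5L),
                         utr3_length_range = c(350L, 500L),
                         utr5_length_range = c(350L, 500L),
                         planted_repeats = NULL,
                         planted_apa = NULL,
                         anatomy_cfg = anatomy_config(),
                         accession_mix = 0.7,
                         apa_target_rep_name = "AluYRa1") {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_chromosomes >= 1L, chrom_length >= 50000L, n_genes >= 1L,
            length(exon_count_range) == 2L,
            exon_count_range[1L] >= 1L,
            exon_count_range[2L] >= exon_count_range[1L],
            utr3_length_range[1L] >= 350L, utr5_length_range[1L] >= 350L,
            utr3_length_range[2L] <= 500L, utr5_length_range[2L] <= 500L,
            inherits(anatomy_cfg, "anatomy_config"),
            accession_mix >= 0, accession_mix <= 1)
  if (!is.null(planted_repeats)) {
    stopifnot(all(c("repName", "category", "orientation", "count") %in%
                    names(planted_repeats)),
              all(planted_repeats$category %in% POSITIONAL_CATEGORIES),
              all(planted_repeats$orientation %in% c("SENSE", "ANTISENSE")))
  }
  if (!is.null(planted_apa)) {
    stopifnot(all(c("region", "count") %in% names(planted_apa)),
              all(planted_apa$region %in% c("POLY_A_TAIL", "A_RICH_LINKER",
                                            "LEFT_ARM", "RIGHT_ARM", "OFF_ELEMENT")))
  }
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
                 exon_count_range = as.integer(exon_count_range),
                 utr3_length_range = as.integer(utr3_length_range),
                 utr5_length_range = as.integer(utr5_length_range),
                 planted_repeats = planted_repeats, planted_apa = planted_apa,
                 anatomy_cfg = anatomy_cfg, accession_mix = accession_mix,
                 apa_target_rep_name = apa_target_rep_name),
            class = "fixture_spec")
}

#' Fixture preset reconstructing the published APA composition
#'
#' A spec planting 100 polyadenylation sites across four genes that each
#' carry a sense-oriented `AluYRa1` spanning the 3'UTR terminus: 40 sites
#' on the elements' poly-A tails, 34 in the A-rich linker, 26 off-element.
#' Joining and summarizing this fixture reproduces the published headline
#' composition (74% of sites on the sense-oriented element; 40% tail, 34%
#' A-rich) as a planted reconstruction.
#'
#' @param seed Integer seed (default 42).
#' @return A [fixture_spec()].
#' @export
fig7_preset <- function(seed = 42L) {
  fixture_spec(
    seed = seed, n_genes = 12L,
    planted_repeats = data.frame(
      repName = "AluYRa1", category = "UTR3_END", orientation = "SENSE",
      count = 4L, stringsAsFactors = FALSE),
    planted_apa = data.frame(
      region = c("POLY_A_TAIL", "A_RICH_LINKER", "OFF_ELEMENT"),
      count = c(40L, 34L, 26L), stringsAsFactors = FALSE))
}

with_fixture_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

rint <- function(lo, hi) if (lo >= hi) as.integer(lo) else
  as.integer(sample(seq.int(lo, hi), 1L))

# Category-specific placement. Margins are chosen against the generator's
# own gene geometry (UTRs 350-500 bp, terminal-exon CDS share 300-450 bp,
# introns 400-700 bp, middle exons 600-900 bp) so that exactly the planted
# category wins precedence.
place_repeat <- function(m, category, L, jt) {
  s <- m$strand
  tb <- terminal_bases(m)
  ex <- m$exons
  k <- nrow(ex)
  place_terminal <- function(t, beyond_high) {
    if (beyond_high) c(t + 131L + jt - L, t + 131L + jt)
    else c(t - 130L - jt, t - 130L - jt + L)
  }
  switch(category,
    UTR3_END = place_terminal(tb$t3, beyond_high = s == "+"),
    UTR5_START = place_terminal(tb$t5, beyond_high = s == "-"),
    ORF_START = if (s == "+") c(m$cdsStart - 40L - jt, m$cdsStart - 40L - jt + L)
                else c(m$cdsEnd + 40L + jt - L, m$cdsEnd + 40L + jt),
    ORF_END = if (s == "+") c(m$cdsEnd + 40L + jt - L, m$cdsEnd + 40L + jt)
              else c(m$cdsStart - 40L - jt, m$cdsStart - 40L - jt + L),
    EXON_SPLICING = {
      if (k < 2L) stop("EXON_SPLICING needs a multi-exon gene", call. = FALSE)
      j0 <- ex[1L, "end"]
      c(j0 - 100L - jt, j0 - 100L - jt + L)
    },
    INSIDE_EXON = {
      if (k == 1L) c(m$cdsStart + 15L + jt, m$cdsStart + 15L + jt + L)
      else if (k >= 3L) c(ex[2L, "start"] + 15L + jt, ex[2L, "start"] + 15L + jt + L)
      else stop("INSIDE_EXON needs a 1- or >=3-exon gene", call. = FALSE)
    },
    UTR3_INTERNAL = if (s == "+") c(m$cdsEnd + 15L + jt, m$cdsEnd + 15L + jt + L)
                    else c(m$cdsStart - 15L - jt - L, m$cdsStart - 15L - jt),
    UTR5_INTERNAL = if (s == "+") c(m$txStart + 15L + jt, m$txStart + 15L + jt + L)
                    else c(m$txEnd - 15L - jt - L, m$txEnd - 15L - jt),
    NO_EXONIC_OVERLAP = {
      if (k < 2L) stop("NO_EXONIC_OVERLAP needs an intron", call. = FALSE)
      c(ex[1L, "end"] + 40L + jt, ex[1L, "end"] + 40L + jt + L)
    },
    stop("unknown category: ", category, call. = FALSE)
  )
}

category_suitable <- function(k, category) {
  switch(category,
    EXON_SPLICING = ,
    NO_EXONIC_OVERLAP = k >= 2L,
    INSIDE_EXON = k == 1L || k >= 3L,
    TRUE)
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Writes `refGene.txt` (extended genePred with bin), `rmsk.txt` (17-column
#' RepeatMasker table), `tapas.tsv` (six-column TAPAS output), `genome.fa`
#' and three `truth_*.tsv` tables into `outdir`, all obeying the dialects
#' of the I/O module. The same seed yields byte-identical files. One
#' representative APA site per gene (preferring a poly-A-tail site; flagged
#' `motif_planted` in the truth table) gets its cleavage context written
#' into the genome: a sense-strand `CA` immediately 5' of the cleavage
#' point and an `AATAAA` hexamer ~25 bp upstream. Neighbouring planted
#' sites can sit a few bases apart, so the context is planted once per
#' gene rather than per site.
#'
#' Infeasible specs (features that cannot fit the generated gene geometry)
#' fail before any file is written.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `files` (named paths), the
#'   generated `genes` (genePred data frame), `reps` (rmsk data frame),
#'   `tapas` data frame, `models`, and `truth` (list of data frames
#'   `repeats`, `apa`, `genes`).
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chromosomes))
    slot <- 20000L
    per_chrom <- (spec$chrom_length - 10000L) %/% slot
    if (ceiling(spec$n_genes / spec$n_chromosomes) > per_chrom)
      stop("infeasible spec: genes do not fit the chromosomes", call. = FALSE)

    genes <- vector("list", spec$n_genes)
    for (i in seq_len(spec$n_genes)) {
      chrom <- chroms[((i - 1L) %% spec$n_chromosomes) + 1L]
      s_idx <- (i - 1L) %/% spec$n_chromosomes
      txStart <- 5000L + s_idx * slot
      k <- rint(spec$exon_count_range[1L], spec$exon_count_range[2L])
      strand <- sample(c("+", "-"), 1L)
      u5 <- rint(spec$utr5_length_range[1L], spec$utr5_length_range[2L])
      u3 <- rint(spec$utr3_length_range[1L], spec$utr3_length_range[2L])
      left_utr <- if (strand == "+") u5 else u3
      right_utr <- if (strand == "+") u3 else u5
      if (k == 1L) {
        elens <- left_utr + right_utr + rint(600L, 900L)
      } else {
        elens <- c(left_utr + rint(300L, 450L),
                   if (k > 2L) vapply(seq_len(k - 2L), function(z) rint(600L, 900L),
                                      integer(1L)) else integer(),
                   right_utr + rint(300L, 450L))
      }
      ilens <- if (k > 1L) vapply(seq_len(k - 1L), function(z) rint(400L, 700L),
                                  integer(1L)) else integer()
      es <- integer(k); ee <- integer(k)
      pos <- txStart
      for (e in seq_len(k)) {
        es[e] <- pos; ee[e] <- pos + elens[e]
        pos <- ee[e] + if (e < k) ilens[e] else 0L
      }
      txEnd <- ee[k]
      if (txEnd + 1000L > spec$chrom_length)
        stop("infeasible spec: gene exceeds chromosome bounds", call. = FALSE)
      acc_pfx <- if (stats::runif(1L) < spec$accession_mix) "NM" else "XM"
      genes[[i]] <- list(
        bin = 0L, name = sprintf("%s_%06d", acc_pfx, 100000L + i),
        chrom = chrom, strand = strand, txStart = txStart, txEnd = txEnd,
        cdsStart = txStart + left_utr, cdsEnd = txEnd - right_utr,
        exonCount = k, exonStarts = es, exonEnds = ee,
        score = 0L, name2 = sprintf("GENE%d", i),
        cdsStartStat = "cmpl", cdsEndStat = "cmpl",
        exonFrames = paste0(paste(rep(0L, k), collapse = ","), ","),
        u3 = u3)
    }
    gp <- data.frame(
      name = vapply(genes, `[[`, character(1L), "name"),
      chrom = vapply(genes, `[[`, character(1L), "chrom"),
      strand = vapply(genes, `[[`, character(1L), "strand"),
      txStart = vapply(genes, `[[`, integer(1L), "txStart"),
      txEnd = vapply(genes, `[[`, integer(1L), "txEnd"),
      cdsStart = vapply(genes, `[[`, integer(1L), "cdsStart"),
      cdsEnd = vapply(genes, `[[`, integer(1L), "cdsEnd"),
      exonCount = vapply(genes, `[[`, integer(1L), "exonCount"),
      stringsAsFactors = FALSE)
    gp$exonStarts <- lapply(genes, `[[`, "exonStarts")
    gp$exonEnds <- lapply(genes, `[[`, "exonEnds")
    gp$score <- 0L
    gp$name2 <- vapply(genes, `[[`, character(1L), "name2")
    gp$cdsStartStat <- "cmpl"; gp$cdsEndStat <- "cmpl"
    gp$exonFrames <- vapply(genes, `[[`, character(1L), "exonFrames")
    gp$bin <- 0L
    attr(gp, "dialect") <- "genePredExtBin"
    models <- transcript_models(gp)

    # --- plant repeats -----------------------------------------------------
    cfg <- spec$anatomy_cfg
    Lmax <- min(310L, cfg$consensus_length)
    Lmin <- min(280L, Lmax)
    rep_rows <- list()
    truth_rep <- list()
    cursor <- 0L
    next_gene <- function(category) {
      for (step in seq_len(spec$n_genes)) {
        cursor <<- (cursor %% spec$n_genes) + 1L
        if (category_suitable(models[[cursor]]$exonCount %||% nrow(models[[cursor]]$exons),
                              category))
          return(cursor)
      }
      stop(sprintf("infeasible spec: no gene suitable for %s", category), call. = FALSE)
    }
    pr <- spec$planted_repeats
    if (!is.null(pr)) {
      for (r in seq_len(nrow(pr))) {
        for (c in seq_len(pr$count[r])) {
          gi <- next_gene(pr$category[r])
          m <- models[[gi]]
          L <- rint(Lmin, Lmax)
          jt <- rint(0L, 10L)
          ab <- place_repeat(m, pr$category[r], L, jt)
          if (ab[1L] < 0L) stop("infeasible spec: repeat before chromosome start",
                                call. = FALSE)
          rstrand <- if (pr$orientation[r] == "SENSE") m$strand else
            setdiff(c("+", "-"), m$strand)
          glen <- ab[2L] - ab[1L]
          idx <- length(rep_rows) + 1L
          rep_rows[[idx]] <- data.frame(
            bin = 0L, swScore = rint(1000L, 3000L), milliDiv = rint(10L, 120L),
            milliDel = rint(0L, 30L), milliIns = rint(0L, 30L),
            genoName = m$chrom, genoStart = ab[1L], genoEnd = ab[2L],
            genoLeft = -(spec$chrom_length - ab[2L]), strand = rstrand,
            repName = pr$repName[r],
            repClass = if ("repClass" %in% names(pr)) pr$repClass[r] else "SINE",
            repFamily = if ("repFamily" %in% names(pr)) pr$repFamily[r] else "Alu",
            repStart = if (rstrand == "+") 1L else -(cfg$consensus_length - glen),
            repEnd = glen,
            repLeft = if (rstrand == "+") -(cfg$consensus_length - glen) else 1L,
            id = idx, stringsAsFactors = FALSE)
          truth_rep[[idx]] <- data.frame(
            rep_row = idx, repName = pr$repName[r], chrom = m$chrom,
            genoStart = ab[1L], genoEnd = ab[2L], repStrand = rstrand,
            gene = m$name2, transcript = m$name,
            category = pr$category[r], orientation = pr$orientation[r],
            stringsAsFactors = FALSE)
        }
      }
    }
    rmsk <- if (length(rep_rows)) do.call(rbind, rep_rows) else {
      data.frame(bin = integer(), swScore = integer(), milliDiv = integer(),
                         milliDel = integer(), milliIns = integer(),
                         genoName = character(), genoStart = integer(),
                         genoEnd = integer(), genoLeft = integer(),
                         strand = character(), repName = character(),
                         repClass = character(), repFamily = character(),
                 repStart = integer(), repEnd = integer(),
                 repLeft = integer(), id = integer(),
                 stringsAsFactors = FALSE)
    }
    truth_repeats <- if (length(truth_rep)) do.call(rbind, truth_rep) else
      data.frame(rep_row = integer(), repName = character(), chrom = character(),
                 genoStart = integer(), genoEnd = integer(), repStrand = character(),
                 gene = character(), transcript = character(), category = character(),
                 orientation = character(), stringsAsFactors = FALSE)

    # --- plant APA sites ---------------------------------------------------
    truth_apa <- data.frame(gene = character(), pos = integer(), region = character(),
                            on_element = logical(), stringsAsFactors = FALSE)
    tapas <- data.frame(gene = character(), chrom = character(), strand = character(),
                        read_count = integer(), stringsAsFactors = FALSE)
    tapas$apa_sites <- list(); tapas$abundances <- list()
    pa <- spec$planted_apa
    if (!is.null(pa) && sum(pa$count) > 0L) {
      elig <- which(truth_repeats$category == "UTR3_END" &
                      truth_repeats$orientation == "SENSE" &
                      truth_repeats$repName == spec$apa_target_rep_name)
      if (!length(elig))
        stop("infeasible spec: planted APA sites need sense UTR3_END elements of ",
             spec$apa_target_rep_name, call. = FALSE)
      # one element per distinct gene
      elig <- elig[!duplicated(truth_repeats$gene[elig])]
      ext <- cfg$polyA_max_extension
      if (ext < 2L) stop("infeasible spec: polyA_max_extension too small for tail sites",
                         call. = FALSE)
      counter <- new.env(parent = emptyenv())
      site_rows <- list()
      turn <- 0L
      for (r in seq_len(nrow(pa))) {
        for (c in seq_len(pa$count[r])) {
          e <- elig[(turn %% length(elig)) + 1L]; turn <- turn + 1L
          tr <- truth_repeats[e, ]
          m <- models[[match(tr$transcript, vapply(models, `[[`, character(1L), "name"))]]
          key <- paste(tr$gene, pa$region[r])
          cnt <- (counter[[key]] %||% 0L); counter[[key]] <- cnt + 1L
          plus <- tr$repStrand == "+"
          glen <- tr$genoEnd - tr$genoStart
          pos <- switch(pa$region[r],
            POLY_A_TAIL = {
              d <- 1L + (cnt %% (ext - 1L))
              if (plus) tr$genoEnd + (d - 1L) else tr$genoStart - d
            },
            A_RICH_LINKER = {
              lo <- cfg$a_linker[1L]; hi <- min(cfg$a_linker[2L], glen)
              cp <- lo + (cnt %% (hi - lo + 1L))
              if (plus) tr$genoStart + (cp - 1L) else tr$genoStart + (glen - cp)
            },
            LEFT_ARM = {
              lo <- min(20L, cfg$left_arm[2L]); hi <- cfg$left_arm[2L]
              cp <- lo + (cnt %% (hi - lo + 1L))
              if (plus) tr$genoStart + (cp - 1L) else tr$genoStart + (glen - cp)
            },
            RIGHT_ARM = {
              lo <- cfg$right_arm[1L] + 5L; hi <- glen - 5L
              if (hi < lo) stop("infeasible spec: element too short for RIGHT_ARM sites",
                                call. = FALSE)
              cp <- lo + (cnt %% (hi - lo + 1L))
              if (plus) tr$genoStart + (cp - 1L) else tr$genoStart + (glen - cp)
            },
            OFF_ELEMENT = {
              if (m$strand == "+") m$cdsEnd + 3L + cnt else m$cdsStart - 4L - cnt
            })
          if (pa$region[r] == "OFF_ELEMENT") {
            near <- any(rmsk$genoName == m$chrom &
                          pos >= rmsk$genoStart - ext & pos < rmsk$genoEnd + ext)
            if (near) stop("infeasible spec: off-element site collides with an element",
                           call. = FALSE)
          }
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            gene = tr$gene, pos = as.integer(pos), region = pa$region[r],
            on_element = pa$region[r] != "OFF_ELEMENT",
            chrom = m$chrom, gstrand = m$strand, stringsAsFactors = FALSE)
        }
      }
      sites <- do.call(rbind, site_rows)
      if (anyDuplicated(sites[c("gene", "pos")]))
        stop("infeasible spec: duplicate planted APA positions within a gene",
             call. = FALSE)
      truth_apa <- sites[c("gene", "pos", "region", "on_element")]
      rownames(truth_apa) <- NULL
      tp <- lapply(split(seq_len(nrow(sites)), sites$gene), function(ix) {
        ix <- ix[order(sites$pos[ix])]
        list(gene = sites$gene[ix[1L]], chrom = sites$chrom[ix[1L]],
             strand = sites$gstrand[ix[1L]], apa_sites = sites$pos[ix],
             abundances = round(stats::runif(length(ix), 0.5, 10), 3L),
             read_count = rint(100L, 5000L))
      })
      tp <- tp[order(names(tp))]
      tapas <- data.frame(gene = vapply(tp, `[[`, character(1L), "gene"),
                          chrom = vapply(tp, `[[`, character(1L), "chrom"),
                          strand = vapply(tp, `[[`, character(1L), "strand"),
                          read_count = vapply(tp, `[[`, integer(1L), "read_count"),
                          stringsAsFactors = FALSE)
      tapas$apa_sites <- lapply(tp, `[[`, "apa_sites")
      tapas$abundances <- lapply(tp, `[[`, "abundances")
      rownames(tapas) <- NULL
      tapas <- tapas[c("gene", "chrom", "strand", "apa_sites", "abundances",
                       "read_count")]
    }

    truth_genes <- data.frame(
      gene = gp$name2, transcript = gp$name, chrom = gp$chrom, strand = gp$strand,
      utr3_len = vapply(genes, `[[`, integer(1L), "u3"), stringsAsFactors = FALSE)

    # --- genome FASTA with planted cleavage context ------------------------
    seqs <- lapply(chroms, function(ch)
      sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE))
    names(seqs) <- chroms
    if (nrow(truth_apa)) {
      # planted sites can sit a few bp apart, so a cleavage context written
      # for every site would overwrite its neighbours'; plant one
      # representative context per gene (preferring a tail site) and flag it
      truth_apa$motif_planted <- FALSE
      for (g_ix in split(seq_len(nrow(truth_apa)), truth_apa$gene)) {
        tail_ix <- g_ix[truth_apa$region[g_ix] == "POLY_A_TAIL"]
        truth_apa$motif_planted[if (length(tail_ix)) tail_ix[1L] else g_ix[1L]] <- TRUE
      }
      for (r in which(truth_apa$motif_planted)) {
        g <- truth_apa$gene[r]
        gi <- match(g, gp$name2)
        ch <- gp$chrom[gi]; gs <- gp$strand[gi]
        p <- truth_apa$pos[r]  # 0-based last transcribed base
        if (gs == "+") {
          seqs[[ch]][p:(p + 1L)] <- c("C", "A")            # 1-based p, p+1
          seqs[[ch]][(p - 24L):(p - 19L)] <- c("A", "A", "T", "A", "A", "A")
        } else {
          seqs[[ch]][(p + 1L):(p + 2L)] <- c("T", "G")     # revcomp of CA
          seqs[[ch]][(p + 21L):(p + 26L)] <- c("T", "T", "T", "A", "T", "T")
        }
      }
    }

    # --- write everything --------------------------------------------------
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    files <- c(genes = file.path(outdir, "refGene.txt"),
               repeats = file.path(outdir, "rmsk.txt"),
               tapas = file.path(outdir, "tapas.tsv"),
               genome = file.path(outdir, "genome.fa"),
               truth_repeats = file.path(outdir, "truth_repeats.tsv"),
               truth_apa = file.path(outdir, "truth_apa.tsv"),
               truth_genes = file.path(outdir, "truth_genes.tsv"))
    write_genepred(gp, files[["genes"]])
    write_rmsk(rmsk, files[["repeats"]])
    write_tapas(tapas, files[["tapas"]])
    dna <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1L), collapse = ""))
    Biostrings::writeXStringSet(dna, filepath = files[["genome"]], width = 70L)
    write_tsv_atomic(truth_repeats, files[["truth_repeats"]])
    write_tsv_atomic(truth_apa, files[["truth_apa"]])
    write_tsv_atomic(truth_genes, files[["truth_genes"]])

    invisible(list(dir = outdir, files = files, genes = gp,
                   reps = normalize_consensus(rmsk), tapas = tapas, models = models,
                   truth = list(repeats = truth_repeats, apa = truth_apa,
                                genes = truth_genes),
                   spec = spec))
  })
}

#' Brute-force per-base positional classification (test oracle)
#'
#' Classifies a repeat x transcript pair by explicitly enumerating every
#' base: exonic bases are labelled 5'UTR/CDS/3'UTR, terminal and ORF
#' boundary bases and junction coordinates are materialized, the repeat's
#' covered base set is intersected with those labels, and the category is
#' derived from the resulting evidence with the same precedence table as
#' [classify_pair()]. No interval arithmetic from the locator is shared;
#' this is the independent oracle the acceptance suite compares the
#' locator against.
#'
#' @inheritParams classify_pair
#' @return The primary category (character scalar).
#' @export
brute_force_classify <- function(rep, model, proximity_bp = 0L) {
  rep <- as_rep_record(rep)
  stopifnot(inherits(model, "transcript_model"))
  if (!identical(as.character(rep$chrom), model$chrom))
    stop("chromosome mismatch", call. = FALSE)
  a <- as.integer(rep$genoStart); b <- as.integer(rep$genoEnd)
  covered <- seq.int(a, b - 1L)
  enum <- function(blocks) {
    if (!nrow(blocks)) return(integer())
    unlist(lapply(seq_len(nrow(blocks)),
                  function(i) seq.int(blocks[i, "start"], blocks[i, "end"] - 1L)))
  }
  exon_bases <- enum(model$exons)
  utr3_bases <- enum(model$utr3_blocks)
  utr5_bases <- enum(model$utr5_blocks)
  tb <- terminal_bases(model)
  ob <- orf_bases(model)
  plus <- model$strand == "+"

  # distance from each covered base to a terminal base; the beyond-end side
  # is offset by one because the transcript boundary coordinate is exclusive
  dist_to <- function(t, beyond_high) {
    d <- if (beyond_high) ifelse(covered > t, covered - t - 1L, t - covered)
         else ifelse(covered < t, t - covered - 1L, covered - t)
    min(d)
  }
  d3 <- dist_to(tb$t3, beyond_high = plus)
  d5 <- dist_to(tb$t5, beyond_high = !plus)

  exonic_cov <- intersect(covered, exon_bases)
  cats <- character()
  if (!model$noncoding && (tb$t3 %in% utr3_bases) && d3 <= proximity_bp)
    cats <- c(cats, "UTR3_END")
  if (!model$noncoding && (tb$t5 %in% utr5_bases) && d5 <= proximity_bp)
    cats <- c(cats, "UTR5_START")
  hit_orf_end <- !is.na(ob$end) && ob$end %in% covered
  hit_orf_start <- !is.na(ob$start) && ob$start %in% covered
  if (hit_orf_end) cats <- c(cats, "ORF_END")
  if (hit_orf_start) cats <- c(cats, "ORF_START")
  spans <- any(vapply(model$internal_junctions,
                      function(j) (j - 1L) %in% covered && j %in% covered,
                      logical(1L)))
  if (spans) cats <- c(cats, "EXON_SPLICING")
  if (length(exonic_cov) && all(exonic_cov %in% utr3_bases) && d3 > 0L)
    cats <- c(cats, "UTR3_INTERNAL")
  if (length(exonic_cov) && all(exonic_cov %in% utr5_bases) && d5 > 0L)
    cats <- c(cats, "UTR5_INTERNAL")
  boundary <- ((tb$t3 %in% utr3_bases) && d3 == 0L) ||
    ((tb$t5 %in% utr5_bases) && d5 == 0L) ||
    hit_orf_start || hit_orf_end || spans
  within_one <- any(vapply(seq_len(nrow(model$exons)), function(i)
    all(covered %in% seq.int(model$exons[i, "start"], model$exons[i, "end"] - 1L)),
    logical(1L)))
  if (length(exonic_cov) && within_one && !boundary) cats <- c(cats, "INSIDE_EXON")
  if (length(exonic_cov) && !length(cats)) cats <- "INSIDE_EXON"
  if (!length(cats)) cats <- "NO_EXONIC_OVERLAP"
  POSITIONAL_CATEGORIES[POSITIONAL_CATEGORIES %in% cats][1L]
}
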