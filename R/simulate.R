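# Synthetic-data generator with planted ground truth. Emulates the study
# design of a pan-cancer proteogenomic screen at desk scale: multi-exon
# transcripts with UTRs and CDS on both strands, planted ncORFs of every
# category, target/decoy PSM score mixtures with known labels, somatic
# variants with known canonical and non-canonical consequences, and epitope
# candidate tables with known filter outcomes.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_codons <- function(n) paste(sample(SENSE_CODONS, n, replace = TRUE),
                                   collapse = "")

#' Simulation configuration
#'
#' Defaults describe the study conditions every planted-truth check runs
#' under: a compact reference (48 transcripts, a quarter noncoding) with one
#' planted ORF per category slot per transcript, 10 cohorts of 5 samples, a
#' two-component PSM score mixture (true targets N(4, 1); false targets and
#' decoys N(0, 1); 10,000 PSMs at 50% decoys), 8 pervasively translated
#' ORFs, and 1 minute of retention-time noise.
#'
#' @param seed root seed; per-generator child seeds are derived from it by
#'   fixed offsets.
#' @param n_transcripts total transcripts in the synthetic reference.
#' @param fraction_noncoding fraction of transcripts that are noncoding.
#' @param planted_orfs_per_category optional named integer vector
#'   (`uORF_5utr`, `dORF_3utr`, `out_of_frame`, `ncRNA`, `miscRNA`)
#'   requesting plant counts; `NULL` plants one per eligible transcript.
#'   Requests exceeding capacity are an error.
#' @param min_planted_codons,max_planted_codons planted protein length
#'   range in codons (short-ORF regime).
#' @param n_cohorts,n_samples_per_cohort cohort structure.
#' @param psm_model list: `n_true`, `n_false`, `true_score_mean`,
#'   `null_score_mean`, `score_sd`, `decoy_fraction`.
#' @param n_immuno immunopeptidome-assay PSMs to emit.
#' @param n_pervasive ORFs planted with true-peptide support in
#'   `pervasive_min_cohorts` or more cohorts.
#' @param pervasive_min_cohorts cohort threshold for pervasive plants.
#' @param variant_model data.frame `canonical_class`, `ncorf_class`, `n`
#'   requesting variants per consequence cell; `NULL` for the default mix.
#' @param n_epitope_candidates epitope candidates to simulate.
#' @param rt_noise_sd_min retention-time noise SD in minutes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 48L,
                       fraction_noncoding = 0.25,
                       planted_orfs_per_category = NULL,
                       min_planted_codons = 10L,
                       max_planted_codons = 26L,
                       n_cohorts = 10L,
                       n_samples_per_cohort = 5L,
                       psm_model = list(n_true = 2500L, n_false = 2500L,
                                        true_score_mean = 4,
                                        null_score_mean = 0,
                                        score_sd = 1, decoy_fraction = 0.5),
                       n_immuno = 300L,
                       n_pervasive = 8L,
                       pervasive_min_cohorts = 8L,
                       variant_model = NULL,
                       n_epitope_candidates = 48L,
                       rt_noise_sd_min = 1) {
  stopifnot(fraction_noncoding >= 0, fraction_noncoding <= 1,
            psm_model$score_sd > 0, n_transcripts >= 1L)
  structure(list(seed = as.integer(seed), n_transcripts = n_transcripts,
                 fraction_noncoding = fraction_noncoding,
                 planted_orfs_per_category = planted_orfs_per_category,
                 min_planted_codons = min_planted_codons,
                 max_planted_codons = max_planted_codons,
                 n_cohorts = n_cohorts,
                 n_samples_per_cohort = n_samples_per_cohort,
                 psm_model = psm_model, n_immuno = n_immuno,
                 n_pervasive = n_pervasive,
                 pervasive_min_cohorts = pervasive_min_cohorts,
                 variant_model = variant_model,
                 n_epitope_candidates = n_epitope_candidates,
                 rt_noise_sd_min = rt_noise_sd_min),
            class = "sim_config")
}

# Plant `TAA + ATG + body + stop` in frame at transcript position t_start
# (the leading in-frame stop guarantees the planted AUG is the 5'-most of
# its (stop, frame) group). Returns the modified sequence and the ORF.
plant_orf_block <- function(seqstr, t_start, n_codons) {
  body <- random_codons(n_codons - 1L)
  stopc <- sample(STOP_CODONS, 1L)
  block <- paste0("TAA", "ATG", body, stopc)
  stopifnot(t_start - 3L >= 0L,
            t_start + 3L * (n_codons + 1L) <= nchar(seqstr))
  substr(seqstr, t_start - 2L, t_start + 3L * (n_codons + 1L)) <- block
  list(seq = seqstr, t_start = t_start, t_end = t_start + 3L * (n_codons + 1L),
       protein = translate_frame(substring(seqstr, t_start + 1L), 0L))
}

# canonical-frame stop check over the region [a, b) of a coding sequence
# whose CDS starts at cds_start (transcript coords)
region_has_canonical_stop <- function(seqstr, cds_start, a, b) {
  first <- cds_start + 3L * max(0L, (a - cds_start - 2L) %/% 3L)
  starts <- seq.int(first, b - 1L, by = 3L)
  starts <- starts[starts >= cds_start & starts + 3L <= nchar(seqstr)]
  any(is_stop_codon(substring(seqstr, starts + 1L, starts + 3L)))
}

#' Generate the synthetic reference: genome, annotation, canonical proteome
#'
#' Protein-coding transcripts carry a 5'UTR / CDS / 3'UTR layout with
#' planted upstream, downstream and out-of-frame ORFs constructed by
#' explicit sequence design (an in-frame `TAA` immediately 5' of each
#' planted AUG pins the ORF start; out-of-frame plants are resampled until
#' they introduce no canonical-frame stop). Noncoding transcripts carry one
#' planted ORF each. Spliced sequences are split into 1-3 exons and placed
#' on both strands; the canonical proteome is the translation of every
#' (post-plant) CDS.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `canonical.fa` and `manifest.json`.
#' @return list: `genome`, `transcripts` (`transcript_set`),
#'   `canonical_db` (`protein_db`), `planted` (data.frame `orf_id`,
#'   `transcript_id`, `category`, `t_start`, `t_end`, `frame_offset`,
#'   `protein`).
#' @export
simulate_reference <- function(cfg = sim_config(), dir = NULL) {
  set.seed(child_seed(cfg$seed, 1L))
  n_nc <- round(cfg$n_transcripts * cfg$fraction_noncoding)
  n_cod <- cfg$n_transcripts - n_nc
  req <- cfg$planted_orfs_per_category
  cap <- c(uORF_5utr = n_cod, dORF_3utr = n_cod, out_of_frame = n_cod,
           ncRNA = ceiling(n_nc * 0.75), miscRNA = floor(n_nc * 0.25))
  if (is.null(req)) {
    req <- cap
  } else {
    full <- stats::setNames(integer(length(cap)), names(cap))
    full[names(req)] <- as.integer(req)
    req <- full
  }
  over <- names(req)[req > cap[names(req)]]
  if (length(over))
    stop("infeasible plant request (exceeds transcript capacity): ",
         paste(over, collapse = ", "))

  planted <- list(); models <- list(); canon <- list()
  contigs <- stats::setNames(rep("", 4L), paste0("chr", 1:4))
  plant_len <- function() sample(cfg$min_planted_codons:cfg$max_planted_codons, 1L)

  make_coding <- function(i) {
    tid <- sprintf("TX%03d", i); gid <- sprintf("GENE%03d", i)
    utr5 <- sample(seq(96L, 150L, 3L), 1L)
    n_codons <- sample(60:100, 1L)
    utr3 <- sample(120:200, 1L)
    cds <- paste0("ATG", random_codons(n_codons - 2L), sample(STOP_CODONS, 1L))
    s <- paste0(random_dna(utr5), cds, random_dna(utr3))
    cds_start <- utr5; cds_end <- utr5 + 3L * n_codons
    plants <- list()
    if (i <= req["uORF_5utr"]) {
      k <- plant_len()
      need <- 3L * (k + 1L)
      u_s <- sample(3:(utr5 - need), 1L)
      p <- plant_orf_block(s, u_s, k); s <- p$seq
      plants$uORF_5utr <- p
    }
    if (i <= req["dORF_3utr"]) {
      k <- plant_len()
      need <- 3L * (k + 1L)
      d_s <- sample((cds_end + 3L):(cds_start + 3L * n_codons + utr3 - need), 1L)
      p <- plant_orf_block(s, d_s, k); s <- p$seq
      plants$dORF_3utr <- p
    }
    if (i <= req["out_of_frame"]) {
      k <- min(plant_len(), (n_codons - 6L))
      need <- 3L * (k + 1L)
      shift <- sample(1:2, 1L)
      lo <- cds_start + 6L + shift
      hi <- cds_end - 3L - need
      cand <- seq(lo, hi, by = 3L)
      ok <- FALSE
      for (try in 1:200) {
        o_s <- sample(cand, 1L)
        p <- plant_orf_block(s, o_s, k)
        if (!region_has_canonical_stop(p$seq, cds_start, o_s - 5L,
                                       p$t_end + 2L)) {
          s <- p$seq; plants$out_of_frame <- p; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not plant an out-of-frame ORF without a ",
                    "canonical-frame stop in transcript ", tid)
    }
    list(tid = tid, gid = gid, s = s, cds_span = c(cds_start, cds_end),
         biotype = "protein_coding", plants = plants)
  }

  make_noncoding <- function(i, idx_nc) {
    tid <- sprintf("TX%03d", i); gid <- sprintf("GENE%03d", i)
    len <- sample(400:800, 1L)
    s <- random_dna(len)
    biotype <- if (idx_nc <= cap["ncRNA"])
      sample(c("lncRNA", "pseudogene"), 1L) else sample(c("misc_RNA", "rRNA"), 1L)
    category <- if (biotype %in% c("misc_RNA", "rRNA")) "miscRNA" else "ncRNA"
    want <- if (category == "ncRNA") idx_nc <= req["ncRNA"] else
      (idx_nc - cap["ncRNA"]) <= req["miscRNA"]
    plants <- list()
    if (want && req[category] > 0L) {
      k <- plant_len()
      need <- 3L * (k + 1L)
      t_s <- sample(3:(len - need), 1L)
      p <- plant_orf_block(s, t_s, k); s <- p$seq
      plants[[category]] <- p
    }
    list(tid = tid, gid = gid, s = s, cds_span = NULL, biotype = biotype,
         plants = plants)
  }

  specs <- vector("list", cfg$n_transcripts)
  for (i in seq_len(n_cod)) specs[[i]] <- make_coding(i)
  for (j in seq_len(n_nc)) specs[[n_cod + j]] <- make_noncoding(n_cod + j, j)

  # place every transcript on a contig (round-robin, alternating strands)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ctg <- names(contigs)[(i - 1L) %% length(contigs) + 1L]
    strand <- if (i %% 2L == 0L) "-" else "+"
    L <- nchar(sp$s)
    n_ex <- sample(1:3, 1L)
    brk <- if (n_ex > 1L) sort(sample(seq(30L, L - 30L), n_ex - 1L)) else integer()
    bounds <- c(0L, brk, L)
    chunks <- substring(sp$s, bounds[-length(bounds)] + 1L, bounds[-1L])
    gchunks <- if (strand == "+") chunks else rev(rc(chunks))
    cur <- nchar(contigs[[ctg]]) + 100L  # 100 nt gap before the transcript
    pieces <- random_dna(100L)
    exons <- data.frame(start = integer(), end = integer())
    for (ci in seq_along(gchunks)) {
      exons <- rbind(exons, data.frame(start = cur,
                                       end = cur + nchar(gchunks[ci])))
      pieces <- paste0(pieces, gchunks[ci])
      cur <- cur + nchar(gchunks[ci])
      if (ci < length(gchunks)) {
        ilen <- sample(60:120, 1L)
        pieces <- paste0(pieces, random_dna(ilen))
        cur <- cur + ilen
      }
    }
    contigs[[ctg]] <- paste0(contigs[[ctg]], pieces)
    m <- transcript_model(sp$tid, sp$gid, sp$gid, ctg, strand, exons,
                          cds_span = sp$cds_span, biotype = sp$biotype)
    models[[sp$tid]] <- m
    if (!is.null(sp$cds_span)) {
      prot <- translate_frame(substring(sp$s, sp$cds_span[1L] + 1L,
                                        sp$cds_span[2L]), 0L)
      canon[[length(canon) + 1L]] <- data.frame(
        accession = paste0("canon|", sp$gid), sequence = prot,
        stringsAsFactors = FALSE)
    }
    for (cat in names(sp$plants)) {
      p <- sp$plants[[cat]]
      planted[[length(planted) + 1L]] <- data.frame(
        orf_id = orf_id_of(sp$tid, p$t_start, p$t_start %% 3L),
        transcript_id = sp$tid, gene_id = sp$gid, category = cat,
        t_start = p$t_start, t_end = p$t_end, frame_offset = p$t_start %% 3L,
        codon_length = (p$t_end - p$t_start) %/% 3L - 1L,
        protein = p$protein, stringsAsFactors = FALSE)
    }
  }

  genome <- genome_build(contigs)
  transcripts <- structure(models, class = "transcript_set",
                           rejected = data.frame(transcript_id = character(),
                                                 reason = character()))
  canon_df <- do.call(rbind, canon)
  canonical_db <- protein_db(canon_df$accession, canon_df$sequence, "canonical")
  planted_df <- do.call(rbind, planted)
  rownames(planted_df) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(genome, file.path(dir, "genome.fa"))
    write_gtf(transcripts, file.path(dir, "annotation.gtf"))
    write_protein_fasta(canonical_db, file.path(dir, "canonical.fa"))
    jsonlite::write_json(planted_df, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  list(genome = genome, transcripts = transcripts,
       canonical_db = canonical_db, planted = planted_df)
}

#' Random background transcripts (no planted structure)
#'
#' Single- or multi-exon noncoding transcripts of random sequence on both
#' strands, one contig each; the workhorse input for oracle-equivalence
#' checks.
#'
#' @param n number of transcripts.
#' @param len_range spliced length range (nt).
#' @param gc_range GC-content range.
#' @param seed RNG seed.
#' @return list `transcripts` (`transcript_set`), `genome`.
#' @export
simulate_random_transcripts <- function(n, len_range = c(300L, 3000L),
                                        gc_range = c(0.3, 0.6), seed = 1L) {
  set.seed(seed)
  models <- list(); contigs <- character()
  for (i in seq_len(n)) {
    L <- sample(len_range[1L]:len_range[2L], 1L)
    gc <- stats::runif(1L, gc_range[1L], gc_range[2L])
    s <- random_dna(L, gc)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(1:3, 1L)
    brk <- if (n_ex > 1L) sort(sample(seq(20L, L - 20L), n_ex - 1L)) else integer()
    bounds <- c(0L, brk, L)
    chunks <- substring(s, bounds[-length(bounds)] + 1L, bounds[-1L])
    gchunks <- if (strand == "+") chunks else rev(rc(chunks))
    ctg <- sprintf("rctg%04d", i)
    cur <- 10L; pieces <- random_dna(10L)
    exons <- data.frame(start = integer(), end = integer())
    for (ci in seq_along(gchunks)) {
      exons <- rbind(exons, data.frame(start = cur,
                                       end = cur + nchar(gchunks[ci])))
      pieces <- paste0(pieces, gchunks[ci])
      cur <- cur + nchar(gchunks[ci])
      if (ci < length(gchunks)) {
        ilen <- sample(40:90, 1L)
        pieces <- paste0(pieces, random_dna(ilen))
        cur <- cur + ilen
      }
    }
    contigs[[ctg]] <- pieces
    tid <- sprintf("RTX%04d", i)
    models[[tid]] <- transcript_model(tid, tid, tid, ctg, strand, exons,
                                      cds_span = NULL, biotype = "lncRNA")
  }
  list(transcripts = structure(models, class = "transcript_set"),
       genome = genome_build(unlist(contigs)))
}

cohort_labels <- function(n) sprintf("C%02d", seq_len(n))

#' Simulate PSM tables with known true/false labels
#'
#' True-target PSMs draw peptides from planted-ORF tryptic digests
#' (excluding peptides contained in canonical sequences) with scores from
#' the high-mean normal; false targets and decoys share the null normal.
#' Probabilities are a logistic transform of the score. Pervasive ORFs are
#' planted by emitting true peptides in `pervasive_min_cohorts` or more
#' cohorts; all other true ORFs are confined to at most 3 home cohorts. A
#' small immunopeptidome-assay set of 8-11-mers is appended.
#'
#' @param cfg a [sim_config()].
#' @param orfs ORF table (typically the planted manifest or the enumeration
#'   output restricted to planted ORFs).
#' @param canonical_db `protein_db` of canonical proteins.
#' @return list: `psms` (PSM data.frame with `is_decoy`), `truth`
#'   (data.frame `spectrum_id`, `is_true`), `pervasive_orfs` (character),
#'   `true_peptides` (data.frame `peptide`, `orf_id`, `cohort`).
#' @export
simulate_psm_tables <- function(cfg, orfs, canonical_db) {
  set.seed(child_seed(cfg$seed, 2L))
  pm <- cfg$psm_model
  full0 <- digest_spec(mode = "full", missed_cleavages = 0L, min_len = 7L,
                       max_len = 25L)
  canon_il <- il_collapse(canonical_db$sequence)
  pool <- lapply(seq_len(nrow(orfs)), function(i) {
    peps <- digest(orfs$protein[i], full0)$peptide
    peps[!vapply(il_collapse(peps), function(p)
      any(grepl(p, canon_il, fixed = TRUE)), logical(1))]
  })
  names(pool) <- orfs$orf_id
  pool <- pool[lengths(pool) > 0L]
  if (!length(pool)) stop("no ORF yields a discriminating tryptic peptide")
  cohorts <- cohort_labels(cfg$n_cohorts)

  n_perv <- min(cfg$n_pervasive, length(pool))
  pervasive <- sample(names(pool), n_perv)
  home <- lapply(stats::setNames(nm = names(pool)), function(o) {
    if (o %in% pervasive) cohorts else
      sample(cohorts, min(3L, length(cohorts)))
  })

  n_targets <- pm$n_true + pm$n_false
  N <- if (pm$decoy_fraction >= 1) stop("decoy_fraction must be < 1") else
    round(n_targets / (1 - pm$decoy_fraction))
  is_decoy <- stats::runif(N) < pm$decoy_fraction
  p_true <- if (n_targets > 0L) pm$n_true / n_targets else 0
  is_true <- !is_decoy & stats::runif(N) < p_true
  score <- ifelse(is_true,
                  stats::rnorm(N, pm$true_score_mean, pm$score_sd),
                  stats::rnorm(N, pm$null_score_mean, pm$score_sd))
  mid <- (pm$true_score_mean + pm$null_score_mean) / 2
  probability <- stats::plogis(3 * (score - mid))

  rand_pep <- function(n) vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, sample(9:15, 1L), replace = TRUE),
          collapse = ""), character(1))

  peptide <- character(N); accessions <- character(N); orf_of <- rep(NA_character_, N)
  cohort <- sample(cohorts, N, replace = TRUE)
  idx_true <- which(is_true)
  if (length(idx_true)) {
    torf <- sample(names(pool), length(idx_true), replace = TRUE)
    peptide[idx_true] <- vapply(torf, function(o) sample(pool[[o]], 1L),
                                character(1))
    accessions[idx_true] <- vapply(torf, function(o) {
      cat <- orfs$category[match(o, orfs$orf_id)]
      orf_accession(o, cat)
    }, character(1))
    orf_of[idx_true] <- torf
    cohort[idx_true] <- vapply(torf, function(o) sample(home[[o]], 1L),
                               character(1))
  }
  idx_false <- which(!is_true & !is_decoy)
  peptide[idx_false] <- rand_pep(length(idx_false))
  accessions[idx_false] <- sample(canonical_db$accession,
                                  length(idx_false), replace = TRUE)
  idx_dec <- which(is_decoy)
  dp <- rand_pep(length(idx_dec))
  peptide[idx_dec] <- vapply(strsplit(dp, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  accessions[idx_dec] <- paste0("rev_", sample(canonical_db$accession,
                                               length(idx_dec), replace = TRUE))

  psms <- data.frame(
    spectrum_id = sprintf("sp%06d", seq_len(N)),
    peptide = peptide, score = score, probability = probability,
    accessions = accessions, cohort = cohort,
    sample_id = paste0(cohort, "_S",
                       sample(cfg$n_samples_per_cohort, N, replace = TRUE)),
    assay = "proteome", is_decoy = is_decoy, stringsAsFactors = FALSE)
  truth_true <- is_true

  # pervasive plants: one guaranteed true peptide per supported cohort
  extra <- list()
  for (o in pervasive) {
    for (co in home[[o]]) {
      sc <- pm$true_score_mean + abs(stats::rnorm(1L, 1, pm$score_sd))
      extra[[length(extra) + 1L]] <- data.frame(
        spectrum_id = sprintf("perv%s_%s", co, o),
        peptide = sample(pool[[o]], 1L), score = sc,
        probability = stats::plogis(3 * (sc - mid)),
        accessions = orf_accession(o, orfs$category[match(o, orfs$orf_id)]),
        cohort = co, sample_id = paste0(co, "_S1"), assay = "proteome",
        is_decoy = FALSE, stringsAsFactors = FALSE)
    }
  }
  # immunopeptidome-assay 8-11-mers from ORF proteins
  n_imm <- cfg$n_immuno
  if (n_imm > 0L) {
    iorf <- sample(names(pool), n_imm, replace = TRUE)
    ipep <- vapply(iorf, function(o) {
      prot <- orfs$protein[match(o, orfs$orf_id)]
      len <- sample(8:11, 1L)
      if (nchar(prot) < len) return(NA_character_)
      a <- sample(nchar(prot) - len + 1L, 1L)
      substr(prot, a, a + len - 1L)
    }, character(1))
    ok <- !is.na(ipep) & !vapply(il_collapse(ipep), function(p)
      any(grepl(p, canon_il, fixed = TRUE)), logical(1))
    sc <- stats::rnorm(sum(ok), pm$true_score_mean, pm$score_sd)
    # confined to each ORF's home cohorts so pervasiveness stays planted
    ico <- vapply(iorf[ok], function(o) sample(home[[o]], 1L), character(1))
    extra[[length(extra) + 1L]] <- data.frame(
      spectrum_id = sprintf("imm%05d", seq_len(sum(ok))),
      peptide = ipep[ok], score = sc,
      probability = stats::plogis(3 * (sc - mid)),
      accessions = vapply(iorf[ok], function(o)
        orf_accession(o, orfs$category[match(o, orfs$orf_id)]), character(1)),
      cohort = ico, sample_id = paste0(ico, "_S1"),
      assay = "immunopeptidome", is_decoy = FALSE, stringsAsFactors = FALSE)
  }
  if (length(extra)) {
    ex <- do.call(rbind, extra)
    psms <- rbind(psms, ex)
    truth_true <- c(truth_true, rep(TRUE, nrow(ex)))
  }
  tt <- which(truth_true)
  true_peptides <- unique(data.frame(
    peptide = psms$peptide[tt],
    orf_id = parse_orf_accession(psms$accessions[tt])$orf_id,
    cohort = psms$cohort[tt], stringsAsFactors = FALSE))
  list(psms = psms, truth = data.frame(spectrum_id = psms$spectrum_id,
                                       is_true = truth_true,
                                       stringsAsFactors = FALSE),
       pervasive_orfs = sort(pervasive), true_peptides = true_peptides)
}

default_variant_model <- function() {
  data.frame(
    canonical_class = c("utr5", "utr3", "silent", "missense", "utr5", "utr3",
                        "utr5", "utr3", "silent", "utr5"),
    ncorf_class = c("missense", "missense", "missense", "missense",
                    "stop_gained", "stop_lost", "frameshift_del",
                    "frameshift_ins", "silent", "inframe_del"),
    n = c(40L, 40L, 30L, 20L, 10L, 8L, 10L, 10L, 15L, 6L),
    stringsAsFactors = FALSE)
}

#' Simulate somatic variants realizing requested consequence cells
#'
#' For each requested (canonical class, ncORF class) cell the generator
#' searches positions and alleles inside planted ORFs of the appropriate
#' category, verifying every candidate with the package's own consequence
#' caller before emitting it (closed loop). Unrealizable cells are skipped
#' with a count. Output is a GDC-dialect MAF data.frame.
#'
#' @param cfg a [sim_config()].
#' @param orfs planted ORF table.
#' @param transcripts `transcript_set`.
#' @param genome `genome_build`.
#' @return list: `maf` (data.frame with GDC columns plus `cohort`),
#'   `manifest` (data.frame `variant_id`, `orf_id`, `canonical_class`,
#'   `ncorf_class`), `skipped` (data.frame of unrealized cells).
#' @export
simulate_variants <- function(cfg, orfs, transcripts, genome) {
  set.seed(child_seed(cfg$seed, 3L))
  model <- if (is.null(cfg$variant_model)) default_variant_model() else
    cfg$variant_model
  cohorts <- cohort_labels(cfg$n_cohorts)
  cat_for <- function(canonical_class) switch(
    canonical_class,
    utr5 = "uORF_5utr", utr3 = "dORF_3utr",
    silent = "out_of_frame", missense = "out_of_frame",
    rna = c("ncRNA", "miscRNA"), "uORF_5utr")

  maf_rows <- list(); man_rows <- list(); skipped <- list()
  for (ri in seq_len(nrow(model))) {
    cc <- model$canonical_class[ri]; nc <- model$ncorf_class[ri]
    want <- model$n[ri]; got <- 0L
    cand_orfs <- orfs[orfs$category %in% cat_for(cc), , drop = FALSE]
    attempts <- 0L
    while (got < want && attempts < want * 400L) {
      attempts <- attempts + 1L
      orf <- cand_orfs[sample(nrow(cand_orfs), 1L), ]
      t <- transcripts[[orf$transcript_id]]
      v <- propose_variant(nc, orf, t, genome)
      if (is.null(v)) next
      # verify on the left-normalized form so emitted MAF rows round-trip
      v <- tryCatch(finalize_variants(v, genome), error = function(e) NULL)
      if (is.null(v)) next
      res <- tryCatch(call_ncorf_consequence(v, orf, t, genome),
                      error = function(e) NULL)
      if (is.null(res) || res$ncorf_class != nc) next
      ccl <- tryCatch(compute_canonical_class(v, t, genome),
                      error = function(e) NA_character_)
      if (is.na(ccl) || ccl != cc) next
      co <- sample(cohorts, 1L)
      sid <- paste0(co, "_S", sample(cfg$n_samples_per_cohort, 1L))
      v$sample_id <- sid; v$cohort <- co
      v$variant_id <- sprintf("%s:%d:%s>%s:%s", v$contig, v$pos0,
                              ifelse(v$ref == "", "-", v$ref),
                              ifelse(v$alt == "", "-", v$alt), sid)
      maf_rows[[length(maf_rows) + 1L]] <- data.frame(
        Hugo_Symbol = orf$transcript_id, Chromosome = v$contig,
        Start_Position = v$pos0 + 1L,
        End_Position = v$pos0 + max(1L, nchar(v$ref)),
        Reference_Allele = ifelse(v$ref == "", "-", v$ref),
        Tumor_Seq_Allele2 = ifelse(v$alt == "", "-", v$alt),
        Variant_Classification = canonical_class_to_maf(cc, v$ref, v$alt),
        Tumor_Sample_Barcode = sid, cohort = co, stringsAsFactors = FALSE)
      man_rows[[length(man_rows) + 1L]] <- data.frame(
        variant_id = v$variant_id, orf_id = orf$orf_id,
        canonical_class = cc, ncorf_class = nc, stringsAsFactors = FALSE)
      got <- got + 1L
    }
    if (got < want)
      skipped[[length(skipped) + 1L]] <- data.frame(
        canonical_class = cc, ncorf_class = nc, missing = want - got,
        stringsAsFactors = FALSE)
  }
  empty_maf <- data.frame(Hugo_Symbol = character(), Chromosome = character(),
                          Start_Position = integer(), End_Position = integer(),
                          Reference_Allele = character(),
                          Tumor_Seq_Allele2 = character(),
                          Variant_Classification = character(),
                          Tumor_Sample_Barcode = character(),
                          cohort = character())
  list(maf = if (length(maf_rows)) do.call(rbind, maf_rows) else empty_maf,
       manifest = if (length(man_rows)) do.call(rbind, man_rows) else
         data.frame(variant_id = character(), orf_id = character(),
                    canonical_class = character(), ncorf_class = character()),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(canonical_class = character(), ncorf_class = character(),
                    missing = integer()))
}

# Propose a genomic edit aimed at one ncORF consequence class; candidate
# only (the caller verifies). Returns a one-row variant data.frame or NULL.
propose_variant <- function(nc, orf, t, genome) {
  s <- spliced_sequence(t, genome)
  cl <- orf$codon_length
  pick_exonic_run <- function(tp, L) {
    gp <- transcript_to_genomic(t, seq.int(tp, tp + L - 1L))
    if (anyNA(gp)) return(NULL)
    gp <- sort(gp)
    if (gp[length(gp)] - gp[1L] + 1L != L) return(NULL)  # spans an intron
    gp
  }
  mk <- function(pos0, ref, alt) data.frame(
    variant_id = "cand", contig = t$contig, pos0 = pos0, ref = ref, alt = alt,
    sample_id = "cand", cohort = "cand", canonical_class = NA_character_,
    stringsAsFactors = FALSE)
  if (nc %in% c("missense", "silent", "stop_gained")) {
    ci <- sample(seq_len(cl - 1L), 1L)  # body codon (not the start codon)
    off <- sample(0:2, 1L)
    tp <- orf$t_start + 3L * ci + off
    gp <- transcript_to_genomic(t, tp)
    if (is.na(gp)) return(NULL)
    ref <- substr(genome[[t$contig]], gp + 1L, gp + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    return(mk(gp, ref, alt))
  }
  if (nc == "stop_lost") {
    off <- sample(0:2, 1L)
    tp <- orf$t_start + 3L * cl + off
    gp <- transcript_to_genomic(t, tp)
    if (is.na(gp)) return(NULL)
    ref <- substr(genome[[t$contig]], gp + 1L, gp + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    return(mk(gp, ref, alt))
  }
  if (nc %in% c("frameshift_del", "inframe_del")) {
    L <- if (nc == "inframe_del") 3L else sample(c(1L, 2L), 1L)
    tp <- orf$t_start + sample(seq(3L, 3L * cl - L), 1L)
    gp <- pick_exonic_run(tp, L)
    if (is.null(gp)) return(NULL)
    ref <- substr(genome[[t$contig]], gp[1L] + 1L, gp[1L] + L)
    return(mk(gp[1L], ref, ""))
  }
  if (nc %in% c("frameshift_ins", "inframe_ins")) {
    L <- if (nc == "inframe_ins") 3L else sample(c(1L, 2L), 1L)
    tp <- orf$t_start + sample(seq(3L, 3L * cl - 1L), 1L)
    gp <- transcript_to_genomic(t, tp)
    if (is.na(gp)) return(NULL)
    ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    anchor <- if (t$strand == "+") gp - 1L else gp
    if (anchor < 0L) return(NULL)
    return(mk(anchor, "", ins))
  }
  NULL
}

#' Simulate epitope-candidate tables with known filter outcomes
#'
#' Candidates are 8-11-mers from ORF proteins. Intended pass/fail states
#' for the affinity, retention-time and expression filters are planted by
#' construction: affinities are drawn below or above the 150 nM gate,
#' observed retention times are the built-in hydrophobicity prediction plus
#' either small noise (pass) or a >5 min offset (fail), and normal-tissue
#' medians are drawn below 1 or above 1.5 TPM. All eight intent
#' combinations are cycled through.
#'
#' @param cfg a [sim_config()].
#' @param orfs ORF table (needs `orf_id`, `gene_id`, `protein`).
#' @return list: `candidates` (data.frame ready for
#'   [prioritize_epitopes()]), `intent` (data.frame of intended flags and
#'   the implied report membership).
#' @export
simulate_epitope_tables <- function(cfg, orfs) {
  set.seed(child_seed(cfg$seed, 4L))
  n <- cfg$n_epitope_candidates
  alleles <- c("HLA-A*02:01", "HLA-A*01:01", "HLA-B*07:02", "HLA-C*07:01")
  combos <- expand.grid(aff = c(TRUE, FALSE), rt = c(TRUE, FALSE),
                        gtex = c(TRUE, FALSE))
  rows <- list()
  for (i in seq_len(n)) {
    orf <- orfs[sample(nrow(orfs), 1L), ]
    len <- sample(8:11, 1L)
    if (nchar(orf$protein) < len) next
    a <- sample(nchar(orf$protein) - len + 1L, 1L)
    pep <- substr(orf$protein, a, a + len - 1L)
    it <- combos[(i - 1L) %% nrow(combos) + 1L, ]
    affinity <- if (it$aff) exp(stats::runif(1L, log(2), log(150))) else
      stats::runif(1L, 200, 5000)
    hi <- hydrophobicity_index(pep)
    rt_pred <- 20 + 1.5 * hi
    rt_obs <- if (it$rt)
      rt_pred + max(-4.5, min(4.5, stats::rnorm(1L, 0, cfg$rt_noise_sd_min)))
    else rt_pred + sample(c(-1, 1), 1L) * stats::runif(1L, 5.5, 15)
    tpm <- if (it$gtex) stats::runif(1L, 0, 0.9) else stats::runif(1L, 1.5, 50)
    co <- sample(cohort_labels(cfg$n_cohorts), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      candidate_id = sprintf("epi%03d", i),
      peptide = pep, orf_id = orf$orf_id,
      gene_id = if ("gene_id" %in% names(orf)) orf$gene_id else NA_character_,
      sample_id = paste0(co, "_S1"), hla_allele = sample(alleles, 1L),
      affinity_nM = affinity, rt_observed_min = rt_obs,
      rt_predicted_min = rt_pred, gtex_median_tpm = tpm, mutated = FALSE,
      intend_aff = it$aff, intend_rt = it$rt, intend_gtex = it$gtex,
      stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, rows)
  rownames(cand) <- NULL
  intent <- cand[, c("candidate_id", "peptide", "orf_id", "intend_aff",
                     "intend_rt", "intend_gtex")]
  intent$intend_reported <- intent$intend_aff &
    (intent$intend_rt | intent$intend_gtex)
  cand <- cand[, setdiff(names(cand), c("intend_aff", "intend_rt",
                                        "intend_gtex"))]
  list(candidates = cand, intent = intent)
}

#' Run every synthetic generator and write the outputs
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return (invisibly) list of all generator outputs.
#' @export
simulate_all <- function(cfg = sim_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(cfg, dir)
  psm <- simulate_psm_tables(cfg, ref$planted, ref$canonical_db)
  write_tsv_table(psm$psms, file.path(dir, "psms.tsv"))
  orfs2 <- ref$planted
  orfs2$gene_id <- vapply(orfs2$transcript_id, function(tid)
    ref$transcripts[[tid]]$gene_id, character(1))
  vars <- simulate_variants(cfg, ref$planted, ref$transcripts, ref$genome)
  write_tsv_table(vars$maf, file.path(dir, "variants.maf"))
  epi <- simulate_epitope_tables(cfg, orfs2)
  write_tsv_table(epi$candidates, file.path(dir, "epitope_candidates.tsv"))
  manifest <- list(planted_orfs = ref$planted,
                   pervasive_orfs = psm$pervasive_orfs,
                   variant_truth = vars$manifest,
                   epitope_intent = epi$intent)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(list(ref = ref, psm = psm, variants = vars, epitopes = epi,
                 config = cfg))
}
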