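# Readers and writers: ms-format text, phased VCF input (via vcfR),
# minimal unphased VCF output, ancestral-allele tables, scan track / BED
# output and the deterministic fixture generator. Coordinates are
# 0-based half-open internally; VCF's 1-based positions are converted at
# the boundary.

#' Read ms-format simulation output
#'
#' Parses the classic text format: a command line, a seed line,
#' replicates delimited by `//` each with `segsites:` and `positions:`
#' lines followed by 0/1 haplotype rows. The 0 allele is mapped to
#' ancestral and 1 to derived (the ms convention). Malformed input is
#' rejected loudly with the offending line number.
#'
#' @param path Path to an ms-format text file.
#' @param locus_length Physical length used to scale the relative
#'   positions (default 1: keep them relative).
#' @return A `replicate_set` whose replicates are [haplotype_window()]s
#'   (with `evaluated_index` at the SNP nearest the locus midpoint).
#' @export
read_ms <- function(path, locus_length = 1) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  if (!length(starts)) stop("no '//' replicate delimiter found: not ms format")
  reps <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    i <- starts[r] + 1L
    if (i > length(lines) || !startsWith(lines[i], "segsites:")) {
      stop("line ", i, ": expected 'segsites:' after '//'")
    }
    S <- as.integer(sub("segsites:\\s*", "", lines[i]))
    if (is.na(S)) stop("line ", i, ": unreadable segsites count")
    if (S == 0L) stop("line ", i, ": replicate with zero segregating sites")
    i <- i + 1L
    if (i > length(lines) || !startsWith(lines[i], "positions:")) {
      stop("line ", i, ": expected 'positions:' line")
    }
    pos <- as.numeric(strsplit(trimws(sub("positions:\\s*", "", lines[i])),
                               "\\s+")[[1]])
    if (length(pos) != S || anyNA(pos)) {
      stop("line ", i, ": positions do not match segsites")
    }
    i <- i + 1L
    rows <- character(0)
    while (i <= length(lines) && nzchar(trimws(lines[i])) &&
           lines[i] != "//") {
      if (grepl("[^01]", lines[i])) {
        stop("line ", i, ": haplotype row contains characters other than 0/1")
      }
      if (nchar(lines[i]) != S) {
        stop("line ", i, ": haplotype row length ", nchar(lines[i]),
             " != segsites ", S)
      }
      rows <- c(rows, lines[i])
      i <- i + 1L
    }
    if (length(rows) < 2L) {
      stop("replicate ", r, " truncated: fewer than 2 haplotype rows")
    }
    alle <- do.call(rbind, lapply(rows, function(x)
      as.integer(strsplit(x, "")[[1]])))
    ev <- which.min(abs(pos - 0.5))
    reps[[r]] <- haplotype_window(alle, positions = pos * locus_length,
                                  evaluated_index = ev,
                                  require_segregating = FALSE)
  }
  new_replicate_set(reps, NULL, NULL, 0L)
}

#' Write replicates as ms-format text
#'
#' @param x A `replicate_set` or list of [haplotype_window()]s.
#' @param path Output path.
#' @param locus_length Divisor turning stored positions back into
#'   relative coordinates on `[0, 1)` (default: taken from the scenario
#'   if available, else 1).
#' @return `path`, invisibly.
#' @export
write_ms <- function(x, path, locus_length = NULL) {
  wins <- if (inherits(x, "replicate_set")) x$replicates else x
  if (is.null(locus_length)) {
    locus_length <- if (inherits(x, "replicate_set") &&
                        !is.null(x$scenario)) x$scenario$locus_length else 1
  }
  n <- wins[[1L]]$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ms", n, length(wins), "-t <theta>"),
               paste(if (inherits(x, "replicate_set") &&
                         !is.null(x$scenario)) x$scenario$seed else 0,
                     "0 0"), ""), con)
  for (w in wins) {
    writeLines("//", con)
    writeLines(paste0("segsites: ", w$S), con)
    writeLines(paste0("positions: ",
                      paste(sprintf("%.10f", w$sites$position / locus_length),
                            collapse = " ")), con)
    writeLines(apply(w$alleles, 1L, paste, collapse = ""), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read an ancestral-allele table
#'
#' Tab-delimited table with columns `site_id`, `ancestral_allele` and
#' optionally `provenance` (e.g. the outgroup the call came from). Sites
#' absent from the table are excluded from analysis by [read_phased()].
#'
#' @param path Path to the TSV file.
#' @return Data frame with the three columns.
#' @export
read_ancestral_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "ancestral_allele") %in% names(tab))) {
    stop("ancestral table needs columns site_id and ancestral_allele")
  }
  if (is.null(tab$provenance)) tab$provenance <- NA_character_
  tab
}

#' Read phased haplotypes from a VCF
#'
#' Loads biallelic SNPs with fully phased genotypes, applies the
#' ancestral-allele table (sites missing from the table, or whose
#' ancestral allele matches neither REF nor ALT, are dropped and
#' counted -- no strand flipping is attempted) and codes alleles
#' 0 = ancestral / 1 = derived. Each diploid sample contributes two
#' haplotype rows.
#'
#' @param path Path to a VCF file (needs the `vcfR` package).
#' @param ancestral Data frame from [read_ancestral_table()].
#' @return A [haplotype_window()] spanning the chromosome, with attribute
#'   `n_dropped` (sites without a usable ancestral call) and positions
#'   converted to 0-based coordinates.
#' @export
read_phased <- function(path, ancestral) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_phased() needs the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt)) || ncol(gt) < 1L) stop("VCF contains no genotypes")
  keep <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  if (any(!keep)) {
    warning(sum(!keep), " non-biallelic-SNP record(s) skipped")
  }
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  n_dropped <- 0L
  cols <- list(); posv <- numeric(0); idv <- character(0)
  anc_sym <- character(0); der_sym <- character(0)
  for (j in which(keep)) {
    g <- gt[j, ]
    if (any(grepl("/", g, fixed = TRUE))) {
      stop("unphased genotype at record ", ids[j])
    }
    a <- do.call(rbind, strsplit(g, "|", fixed = TRUE))
    if (ncol(a) != 2L || any(!a %in% c("0", "1"))) {
      stop("unreadable genotype at record ", ids[j])
    }
    hap <- as.integer(t(a))            # sample1_a, sample1_b, sample2_a, ...
    m <- match(ids[j], ancestral$site_id)
    if (is.na(m)) { n_dropped <- n_dropped + 1L; next }
    anc <- ancestral$ancestral_allele[m]
    ref <- fix[j, "REF"]; alt <- fix[j, "ALT"]
    if (anc == ref) {
      der <- alt
    } else if (anc == alt) {
      hap <- 1L - hap
      der <- ref
    } else {
      n_dropped <- n_dropped + 1L
      next
    }
    if (sum(hap) == 0L || sum(hap) == length(hap)) next  # monomorphic
    cols[[length(cols) + 1L]] <- hap
    posv <- c(posv, as.numeric(fix[j, "POS"]) - 1)       # 0-based
    idv <- c(idv, ids[j])
    anc_sym <- c(anc_sym, anc); der_sym <- c(der_sym, der)
  }
  if (!length(cols)) {
    warning("no usable site: every record lacked an ancestral call or ",
            "was monomorphic")
    return(NULL)
  }
  o <- order(posv)
  win <- haplotype_window(do.call(cbind, cols)[, o, drop = FALSE],
                          positions = posv[o], site_ids = idv[o],
                          ancestral_allele = anc_sym[o],
                          derived_allele = der_sym[o],
                          require_segregating = FALSE)
  attr(win, "n_dropped") <- n_dropped
  win
}

#' Write a genotype matrix as a minimal unphased VCF
#'
#' Companion to [diploidize()]: exports 0/1/2 genotype codes as unphased
#' `GT` fields so external phasing tools can be run, with re-import via
#' [read_phased()]. Positions are written 1-based per the VCF
#' convention.
#'
#' @param genotypes Integer matrix from [diploidize()] (individuals by
#'   sites, codes 0/1/2) with a `positions` attribute, or any such
#'   matrix.
#' @param path Output path.
#' @param chrom Chromosome label.
#' @param ref,alt REF/ALT allele symbols (recycled over sites).
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, path, chrom = "1",
                                ref = "A", alt = "G") {
  pos <- attr(genotypes, "positions")
  if (is.null(pos)) pos <- seq_len(ncol(genotypes))
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("s", seq_len(ncol(genotypes)))
  inds <- rownames(genotypes)
  if (is.null(inds)) inds <- paste0("ind", seq_len(nrow(genotypes)))
  ref <- rep_len(ref, ncol(genotypes))
  alt <- rep_len(alt, ncol(genotypes))
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=hacsweep_", utils::packageVersion("hacsweep")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", inds), collapse = "\t")),
             con)
  for (j in seq_len(ncol(genotypes))) {
    writeLines(paste(c(chrom, format(round(pos[j]) + 1, scientific = FALSE),
                       ids[j], ref[j], alt[j], ".", "PASS", ".", "GT",
                       gt_code[genotypes[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Reproducibility header for delimited outputs
#'
#' @param seed Master seed of the run.
#' @param config Any R object describing the run configuration; hashed
#'   when the `rlang` package is available.
#' @return Character vector of `#`-prefixed header lines.
#' @export
repro_header <- function(seed = NA, config = NULL) {
  h <- if (!is.null(config) && requireNamespace("rlang", quietly = TRUE)) {
    rlang::hash(config)
  } else NA_character_
  c(paste0("# hacsweep ", utils::packageVersion("hacsweep")),
    paste0("# seed: ", seed),
    paste0("# config_hash: ", h))
}

#' Write a scan track as delimited text
#'
#' @param track A `scan_track`.
#' @param path Output path.
#' @param seed,config Passed to [repro_header()].
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  writeLines(repro_header(seed, config), con)
  close(con)
  suppressWarnings(utils::write.table(track, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' Write flagged clusters as BED intervals
#'
#' 0-based half-open intervals, one per cluster.
#'
#' @param clusters Data frame from [scan_clusters()].
#' @param path Output path.
#' @param chrom Chromosome label for the first BED column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(clusters, path, chrom = "chr1") {
  bed <- data.frame(chrom = chrom,
                    start = floor(clusters$start_pos),
                    end = floor(clusters$end_pos) + 1,
                    name = paste0("svd_cluster_", seq_len(nrow(clusters))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a directory of small deterministic test inputs
#'
#' Writes (a) a neutral ms file, (b) an ongoing-sweep ms file
#' (`s = 0.15`, `f = 0.75`), (c) a toy phased VCF of 4 diploid samples
#' with its ancestral-allele table, and (d) a JSON manifest of Svd values
#' recomputed from the written files. All content is a deterministic
#' function of the seed. The mutation rate is kept small so the fixtures
#' stay a few kilobytes.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_reps Replicates per ms file.
#' @param theta Population mutation rate of the fixture scenarios.
#' @return Invisible character vector of the files written.
#' @export
make_fixture <- function(dir, seed = 1L, n_reps = 3L, theta = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  neutral <- simulate_neutral(
    scenario_config(n = 50, theta = theta, seed = seed), n_reps)
  sweep <- simulate_sweep(
    scenario_config(n = 50, theta = theta,
                    selection = list(s = 0.15, f = 0.75),
                    seed = seed + 1L), n_reps)
  f_ms_n <- file.path(dir, "neutral.ms")
  f_ms_s <- file.path(dir, "sweep.ms")
  write_ms(neutral, f_ms_n, locus_length = neutral$scenario$locus_length)
  write_ms(sweep, f_ms_s, locus_length = sweep$scenario$locus_length)
  # toy phased VCF: 4 diploids = 8 haplotypes, 5 sites
  set.seed(seed + 2L)
  toy <- simulate_replicate(scenario_config(n = 8, theta = 3,
                                            seed = seed + 2L),
                            min_flank = 2L)
  ncol_use <- min(5L, toy$S)
  toy <- subset_sites(toy, seq_len(ncol_use))
  f_vcf <- file.path(dir, "toy_phased.vcf")
  con <- file(f_vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("samp", 1:4)),
                     collapse = "\t")), con)
  for (j in seq_len(toy$S)) {
    gts <- vapply(1:4, function(i)
      paste0(toy$alleles[2 * i - 1, j], "|", toy$alleles[2 * i, j]), "")
    writeLines(paste(c("1", format(round(toy$sites$position[j]) + 1,
                                   scientific = FALSE),
                       toy$sites$site_id[j], toy$sites$ancestral_allele[j],
                       toy$sites$derived_allele[j], ".", "PASS", ".", "GT",
                       gts), collapse = "\t"), con)
  }
  close(con)
  f_anc <- file.path(dir, "toy_ancestral.tsv")
  utils::write.table(data.frame(site_id = toy$sites$site_id,
                                ancestral_allele = toy$sites$ancestral_allele,
                                provenance = "synthetic_truth"),
                     f_anc, sep = "\t", quote = FALSE, row.names = FALSE)
  # manifest: Svd recomputed from the files just written
  S_fix <- 11L
  manifest <- list(
    seed = seed,
    neutral_svd = replicate_statistics(read_ms(f_ms_n), S_fix),
    sweep_svd = replicate_statistics(read_ms(f_ms_s), S_fix),
    window_size = S_fix)
  manifest$neutral_svd <- as.numeric(manifest$neutral_svd)
  manifest$sweep_svd <- as.numeric(manifest$sweep_svd)
  f_man <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(f_ms_n, f_ms_s, f_vcf, f_anc, f_man))
}
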