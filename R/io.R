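stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("mrsub_numerical_error", "error")))
}
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("mrsub_input_error", "error")))
}

#' Read alignment columns from a MAF file
#'
#' Parses multiz-style MAF blocks (`s src start size strand srcSize text`
#' rows).  The species name is the part of `src` before the first dot.
#' Gap characters stay `-`; IUPAC ambiguity codes are preserved; species
#' absent from a block are `NA` (unaligned).  Target genome coordinates are
#' computed per column (0-based, converted to the plus strand when the
#' target row is on `-`); columns where the target carries a gap or an
#' ambiguity code are flagged `skipped` and have `NA` positions when gapped.
#'
#' @param path MAF file path.
#' @param target Target species name.
#' @param species Optional fixed species set (rows of the result).
#' @return List with `cols` (species x sites character matrix), `chrom`,
#'   `pos`, `skipped`.
#' @export
read_maf_columns <- function(path, target, species = NULL) {
  if (!file.exists(path)) stop_input("MAF file not found: ", path)
  lines <- readLines(path)
  blocks <- list()
  cur <- character(0)
  for (ln in c(lines, "")) {
    if (grepl("^s\\s", ln)) {
      cur <- c(cur, ln)
    } else if (grepl("^[a]\\s|^$", ln)) {
      if (length(cur)) blocks[[length(blocks) + 1]] <- cur
      cur <- character(0)
    } else if (!grepl("^#|^[iqe]\\s|^track|^\\s*$", ln)) {
      stop_input("malformed MAF line: ", substr(ln, 1, 60))
    }
  }
  parsed <- lapply(seq_along(blocks), function(bi) {
    fld <- lapply(strsplit(blocks[[bi]], "\\s+"), function(f) {
      if (length(f) != 7) stop_input("malformed MAF s-line in block ", bi)
      f
    })
    src <- vapply(fld, `[`, "", 2)
    sp <- sub("\\..*$", "", src)
    chrom <- ifelse(grepl(".", src, fixed = TRUE), sub("^[^.]*\\.", "", src), src)
    start <- as.numeric(vapply(fld, `[`, "", 3))
    size <- as.numeric(vapply(fld, `[`, "", 4))
    strand <- vapply(fld, `[`, "", 5)
    srcsize <- as.numeric(vapply(fld, `[`, "", 6))
    txt <- toupper(vapply(fld, `[`, "", 7))
    w <- unique(nchar(txt))
    if (length(w) != 1) stop_input("ragged MAF block ", bi)
    list(sp = sp, chrom = chrom, start = start, strand = strand,
         srcsize = srcsize, mat = do.call(rbind, strsplit(txt, "")), width = w)
  })
  parsed <- Filter(function(b) target %in% b$sp, parsed)
  if (!length(parsed)) stop_input("no MAF block contains target ", target)
  all_sp <- if (is.null(species)) unique(unlist(lapply(parsed, `[[`, "sp"))) else species
  if (!target %in% all_sp) all_sp <- c(target, all_sp)
  out_cols <- list(); out_chrom <- list(); out_pos <- list()
  for (b in parsed) {
    M <- matrix(NA_character_, length(all_sp), b$width,
                dimnames = list(all_sp, NULL))
    keep <- b$sp %in% all_sp & !duplicated(b$sp)
    M[b$sp[keep], ] <- b$mat[keep, , drop = FALSE]
    ti <- which(b$sp == target)[1]
    trow <- b$mat[ti, ]
    off <- cumsum(trow != "-") - 1
    pos <- b$start[ti] + off
    if (b$strand[ti] == "-") pos <- b$srcsize[ti] - 1 - pos
    pos[trow == "-"] <- NA
    out_cols[[length(out_cols) + 1]] <- M
    out_chrom[[length(out_chrom) + 1]] <- rep(b$chrom[ti], b$width)
    out_pos[[length(out_pos) + 1]] <- pos
  }
  cols <- do.call(cbind, out_cols)
  skipped <- is_missing_symbol(cols[target, ])
  list(cols = cols, chrom = unlist(out_chrom), pos = unlist(out_pos),
       skipped = skipped)
}

#' Write columns as a single-block MAF file
#'
#' Inverse of [read_maf_columns()] for in-memory column sets: species with
#' `NA` symbols in a column are written as gaps.
#'
#' @param cols Character matrix (species x sites).
#' @param path Output path.
#' @param chrom Chromosome name used for every row.
#' @param start 0-based start of the target row.
#' @param target Target species (first row written, defines coordinates).
#' @export
write_maf <- function(cols, path, target, chrom = "chrSim", start = 0) {
  sp <- c(target, setdiff(rownames(cols), target))
  n <- ncol(cols)
  lines <- c("##maf version=1", "a score=0")
  for (s in sp) {
    seqtxt <- cols[s, ]
    seqtxt[is.na(seqtxt)] <- "-"
    size <- sum(seqtxt != "-")
    lines <- c(lines, sprintf("s %s.%s %d %d + %d %s", s, chrom,
                              if (s == target) start else 0L, size,
                              start + n + 1000L, paste(seqtxt, collapse = "")))
  }
  writeLines(c(lines, ""), path)
  invisible(path)
}

#' Reservoir-sample alignment columns
#'
#' Seed-reproducible uniform sample of `n` columns (all columns when fewer
#' are available), optionally restricted to BED regions first.
#'
#' @param colset Result of [read_maf_columns()].
#' @param n Sample size.
#' @param seed Optional RNG seed.
#' @param bed Optional data.frame from [read_bed()]; only columns whose
#'   target position falls in a region are eligible.
#' @export
sample_columns <- function(colset, n, seed = NULL, bed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  idx <- seq_len(ncol(colset$cols))
  if (!is.null(bed)) {
    ok <- !is.na(colset$pos)
    hit <- rep(FALSE, length(idx))
    sites <- data.frame(chrom = colset$chrom, pos = colset$pos)
    sites$pos[!ok] <- -1
    mp <- map_sites_to_regions(sites, bed)
    hit[unique(mp$site)] <- TRUE
    idx <- idx[hit]
  }
  if (!length(idx)) stop_input("no columns to sample from")
  # reservoir over the (possibly filtered) stream
  res <- idx[seq_len(min(n, length(idx)))]
  if (length(idx) > n) {
    for (i in (n + 1):length(idx)) {
      j <- sample.int(i, 1)
      if (j <= n) res[j] <- idx[i]
    }
  }
  res <- sort(res)
  list(cols = colset$cols[, res, drop = FALSE], chrom = colset$chrom[res],
       pos = colset$pos[res], skipped = colset$skipped[res], index = res)
}

#' Read a BED file (0-based half-open)
#' @param path File path.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !grepl("^(#|track|browser)", ln)]
  fld <- strsplit(ln, "\t| +")
  for (i in seq_along(fld)) {
    f <- fld[[i]]
    if (length(f) < 3 || is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3]))))
      stop_input("malformed BED line ", i)
  }
  data.frame(chrom = vapply(fld, `[`, "", 1),
             start = as.numeric(vapply(fld, `[`, "", 2)),
             end = as.numeric(vapply(fld, `[`, "", 3)),
             name = vapply(fld, function(f) if (length(f) >= 4) f[4] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' Read a two-column region-to-tissue label table (TSV, no header required)
#' @param path File path.
#' @export
read_tissue_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = c("region", "tissue"))
  df
}

#' Write per-site estimates as TSV
#'
#' One row per scored (non-skipped) site: chrom, 0-based position, target
#' base, t_MRS, sigma, q, log likelihood.
#'
#' @param est data.frame from [estimate_columns()].
#' @param chrom,pos Coordinates per column.
#' @param path Output path.
#' @export
write_site_table <- function(est, chrom, pos, path) {
  keep <- !est$skipped
  if (any(!keep)) message(sum(!keep), " skipped site(s) not emitted")
  df <- data.frame(chrom = chrom[keep], pos = pos[keep],
                   target_base = est$target_base[keep],
                   t_mrs = est$tmrs[keep], sigma = est$sigma[keep],
                   q = est$q[keep], logZ = est$logZ[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete offline fixture set
#'
#' Produces, under `dir`: a Newick tree (random coalescent topology scaled
#' to a given depth), a model parameter file (the packaged default rates),
#' a single-block MAF of forward-simulated, gap-masked columns, the truth
#' TSV (`true_T`, `true_q` per column), a BED of regions tiling the fake
#' chromosome, and a region-to-tissue label table.  Everything needed to
#' exercise every subcommand without downloads.
#'
#' @param dir Output directory (created if needed).
#' @param n_taxa Number of species.
#' @param depth Root-to-tip depth in substitutions/site.
#' @param n_sites Number of alignment columns.
#' @param target Target species name (`"sp1"`).
#' @param gap If `TRUE`, apply the synthetic logistic gap mask.
#' @param seed RNG seed.
#' @param model Rate model (default: packaged parameters).
#' @return Named list of file paths plus the simulated truth.
#' @export
fixture_generator <- function(dir, n_taxa = 12, depth = 1.0, n_sites = 200,
                              target = "sp1", gap = TRUE, seed = 1,
                              model = default_model()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  phy <- ape::rcoal(n_taxa, tip.label = paste0("sp", seq_len(n_taxa)))
  phy$edge.length <- phy$edge.length * depth / max(ape::node.depth.edgelength(phy))
  tree <- as_phylo_tree(phy)
  tree_path <- file.path(dir, "tree.nwk")
  write_newick(tree, tree_path)
  model_path <- file.path(dir, "model.txt")
  write_model(model, model_path)
  sim <- forward_simulate(tree, model, n_sites, target)
  cols <- sim$cols
  if (gap) {
    tmpl <- synthetic_gap_template(tree, target, n_sites)
    cols <- apply_gap_mask(cols, tmpl, target)
  }
  maf_path <- file.path(dir, "alignment.maf")
  write_maf(cols, maf_path, target)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(data.frame(pos = seq_len(n_sites) - 1,
                                true_T = sim$true_T, true_q = sim$true_q),
                     truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nreg <- max(2L, n_sites %/% 25L)
  width <- n_sites %/% nreg
  bed <- data.frame(chrom = "chrSim",
                    start = (seq_len(nreg) - 1) * width,
                    end = pmin((seq_len(nreg) - 1) * width + width, n_sites),
                    name = paste0("enh", seq_len(nreg)))
  bed_path <- file.path(dir, "regions.bed")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tissues <- c("brain", "liver", "heart")
  tt <- data.frame(region = bed$name,
                   tissue = sample(tissues, nreg, replace = TRUE))
  tissue_path <- file.path(dir, "tissues.tsv")
  utils::write.table(tt, tissue_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(tree = tree_path, model = model_path, maf = maf_path,
       truth = truth_path, bed = bed_path, tissues = tissue_path,
       target = target, sim = sim)
}
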