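#' Concestor tables
#'
#' An ordered table of named concestor nodes on the target lineage with
#' their times from the present in substitutions per site; the first entry
#' is the target itself at time 0 and the last is the root at the full
#' lineage length.
#'
#' @param names Concestor names, most recent first.
#' @param times Strictly increasing times; `times[1]` must be 0.
#' @return data.frame of class `concestor_table`.
#' @export
concestor_table <- function(names, times) {
  stopifnot(length(names) == length(times), length(times) >= 2)
  if (times[1] != 0) stop("first concestor (the target) must have time 0")
  if (any(diff(times) <= 0)) stop("concestor times must be strictly increasing")
  structure(data.frame(name = as.character(names), time = as.numeric(times),
                       stringsAsFactors = FALSE),
            class = c("concestor_table", "data.frame"))
}

#' @rdname concestor_table
#' @param lineage A [target_lineage][extract_lineage()].
#' @export
concestor_table_from_lineage <- function(lineage) {
  nm <- lineage$names
  nm[is.na(nm)] <- c(lineage$target, paste0("c", seq_len(lineage$M)))[is.na(nm)]
  concestor_table(nm, lineage$time)
}

#' Reduce a concestor table by grouping adjacent concestors
#'
#' @param table A [concestor_table()].
#' @param grouping Character vector, one reduced name per full concestor in
#'   table order; must be order-preserving (each reduced name occupies a
#'   contiguous block).  The reduced concestor takes the time of the most
#'   recent (first) full concestor of its block.
#' @export
reduce_concestors <- function(table, grouping) {
  stopifnot(length(grouping) == nrow(table))
  r <- rle(grouping)
  if (anyDuplicated(r$values)) stop("grouping must be order-preserving (contiguous blocks)")
  first <- cumsum(c(1, utils::head(r$lengths, -1)))
  concestor_table(r$values, table$time[first])
}

#' Assign the smallest concestor interval containing the confidence interval
#'
#' A site is assigned only if `q < q_threshold`; its confidence interval
#' `[tmrs - z sigma, tmrs + z sigma]` is clipped to `[0, tbar]` and the
#' smallest-span pair of concestor times strictly containing it is chosen
#' (containment is closed at the clipped leaf/root boundaries, so a CI
#' touching the present or the root remains assignable).
#'
#' @param tmrs,sigma,q Site estimates (vectors).
#' @param table A [concestor_table()].
#' @param q_threshold Assignment threshold on `q`.
#' @param z Half-width of the confidence interval in standard deviations.
#' @return data.frame with `late`, `early` (concestor names, `NA` when
#'   unassigned) and `reason` (`assigned`, `q-fail`, or `skipped`).
#' @export
assign_interval <- function(tmrs, sigma, q, table, q_threshold = 0.01, z = 2) {
  tbar <- table$time[nrow(table)]
  n <- length(tmrs)
  late <- early <- rep(NA_character_, n)
  reason <- rep("skipped", n)
  tm <- table$time
  for (i in seq_len(n)) {
    if (is.na(tmrs[i]) || is.na(q[i])) next
    if (q[i] >= q_threshold) { reason[i] <- "q-fail"; next }
    lo <- max(0, tmrs[i] - z * sigma[i])
    hi <- min(tbar, tmrs[i] + z * sigma[i])
    best <- NULL; best_span <- Inf
    for (a in seq_len(nrow(table) - 1)) {
      if (!(tm[a] < lo || tm[a] == 0)) next
      for (b in (a + 1):nrow(table)) {
        if (!(tm[b] > hi || tm[b] == tbar)) next
        span <- tm[b] - tm[a]
        if (span < best_span) { best <- c(a, b); best_span <- span }
        break  # later b only widens the span
      }
    }
    if (!is.null(best)) {
      late[i] <- table$name[best[1]]
      early[i] <- table$name[best[2]]
      reason[i] <- "assigned"
    } else {
      reason[i] <- "CI-uncontainable"
    }
  }
  data.frame(late = late, early = early, reason = reason,
             stringsAsFactors = FALSE)
}

#' Map scored sites to genomic regions
#'
#' Interval intersection of single-base sites against 0-based half-open BED
#' regions; a site is reported for every region overlapping it.
#'
#' @param sites data.frame with `chrom` and 0-based `pos`.
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @return data.frame with `site` (row index into `sites`) and `region`
#'   (row index into `regions`), sorted by site then region.
#' @export
map_sites_to_regions <- function(sites, regions) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    ri <- which(regions$chrom == ch)
    if (!length(ri) || !length(si)) next
    qry <- IRanges::IRanges(start = sites$pos[si] + 1L, width = 1L)
    sub <- IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri])
    hits <- IRanges::findOverlaps(qry, sub)
    if (length(hits))
      out[[ch]] <- data.frame(site = si[S4Vectors::queryHits(hits)],
                              region = ri[S4Vectors::subjectHits(hits)])
  }
  if (!length(out)) return(data.frame(site = integer(0), region = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$site, res$region), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hypergeometric enrichment of attribute pairs over a universe
#'
#' For every (tissue set, interval set) pair over a common universe of
#' items: the upper-tail hypergeometric probability
#' `P(X >= observed)` of drawing `observed` tissue items in `n` interval
#' draws from `N` items of which `K` carry the tissue label, the fold
#' enrichment `observed / (n K / N)`, and the standardized deviate
#' `Z = (observed - nK/N) / sd`.  Records are sorted by decreasing Z within
#' tissue.
#'
#' @param universe Character vector of item ids.
#' @param tissue_sets Named list of character vectors (subsets of universe).
#' @param interval_sets Named list of character vectors.
#' @return data.frame with columns `tissue`, `interval`, `z`,
#'   `neg_log10_p`, `enrichment`, `observed`, `expected`, `K`, `n`, `N`.
#' @export
hypergeometric_enrichment <- function(universe, tissue_sets, interval_sets) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  rows <- list()
  for (ti in names(tissue_sets)) {
    tset <- intersect(tissue_sets[[ti]], universe)
    K <- length(tset)
    for (iv in names(interval_sets)) {
      iset <- intersect(interval_sets[[iv]], universe)
      n <- length(iset)
      obs <- length(intersect(tset, iset))
      expct <- n * K / N
      v <- if (N > 1) n * (K / N) * (1 - K / N) * (N - n) / (N - 1) else 0
      z <- if (v > 0) (obs - expct) / sqrt(v) else 0
      p <- stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1]] <-
        data.frame(tissue = ti, interval = iv, z = z,
                   neg_log10_p = -log10(max(p, .Machine$double.xmin)),
                   enrichment = if (expct > 0) obs / expct else 0,
                   observed = obs, expected = expct, K = K, n = n, N = N,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tissue, -out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-level tissue-by-interval enrichment
#'
#' Aggregates site assignments to regions (a region "has" an interval if at
#' least one of its sites is assigned to it), takes as universe all regions
#' with at least one assigned site, and runs
#' [hypergeometric_enrichment()] against a region-to-tissue label table.
#'
#' @param assignments Output of [assign_interval()] (one row per site).
#' @param site_map Output of [map_sites_to_regions()].
#' @param region_ids Character ids, one per region row used in `site_map`.
#' @param tissue_table data.frame with columns `region` (id) and `tissue`.
#' @export
enrich_regions <- function(assignments, site_map, region_ids, tissue_table) {
  asg <- assignments$reason == "assigned"
  hit <- site_map[asg[site_map$site], , drop = FALSE]
  if (!nrow(hit)) stop("no assigned sites overlap any region")
  iv <- paste(assignments$late[hit$site], assignments$early[hit$site], sep = "-")
  rid <- region_ids[hit$region]
  universe <- unique(rid)
  interval_sets <- lapply(split(rid, iv), unique)
  tissue_sets <- lapply(split(as.character(tissue_table$region),
                              tissue_table$tissue), unique)
  hypergeometric_enrichment(universe, tissue_sets, interval_sets)
}
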