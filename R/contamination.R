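#' Screen host elements for foreign TE fragments
#'
#' Seed-and-extend screen for fragments of foreign (donor) families nested
#' inside annotated elements. Exact shared k-mers (default 20-mers, both
#' donor orientations) seed ungapped extensions in both directions that
#' continue while the running identity of the extended match stays at or
#' above `min_identity`; extended matches of at least `min_match` nt are
#' reported, and overlapping matches of the same host/donor-family pair
#' are merged. Any verbatim planted fragment of length
#' `>= max(min_match, seed_length)` is therefore always reported.
#'
#' External BLASTN tabular hits can be used instead via
#' [import_blast_hits()].
#'
#' @param hosts named character vector of host element sequences.
#' @param donors named character vector of donor exemplar sequences; donor
#'   family labels are taken from `donor_families` or the donor names.
#' @param donor_families optional character vector mapping each donor to
#'   its family.
#' @param seed_length exact seed length (nt).
#' @param min_match minimum reported match length (nt).
#' @param min_identity minimum running identity during extension.
#' @return data.frame of hits: `host`, `donor_family`, `host_start`,
#'   `host_end` (0-based half-open), `length`, `identity`.
#' @export
contamination_screen <- function(hosts, donors, donor_families = NULL,
                                 seed_length = 20L, min_match = 100L,
                                 min_identity = 0.8) {
  stopifnot(!is.null(names(hosts)), !is.null(names(donors)))
  if (is.null(donor_families)) donor_families <- names(donors)
  hosts <- toupper(hosts); donors <- toupper(donors)

  # donor seeds in both orientations
  dseq <- c(donors, stats::setNames(revcomp(donors),
                                    paste0(names(donors), "__rc")))
  dfam <- c(donor_families, donor_families)
  didx <- build_index(dseq, seed_length, set_label = "donors")

  empty <- data.frame(host = character(0), donor_family = character(0),
                      host_start = integer(0), host_end = integer(0),
                      length = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  raw <- list(); k <- 0L
  for (hi in seq_along(hosts)) {
    H <- hosts[[hi]]
    nH <- nchar(H)
    if (nH < seed_length) next
    starts <- 0:(nH - seed_length)
    kmers <- substring(H, starts + 1L, starts + seed_length)
    keep <- !grepl("N", kmers, fixed = TRUE)
    q <- data.table(kmer = kmers[keep], hpos = starts[keep])
    seeds <- didx$dt[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(seeds) == 0L) next
    hc <- strsplit(H, "", fixed = TRUE)[[1]]
    for (si in seq_len(nrow(seeds))) {
      D <- dseq[[seeds$reference[si]]]
      dc <- strsplit(D, "", fixed = TRUE)[[1]]
      ext <- .extend_ungapped(hc, dc, seeds$hpos[si], seeds$position[si],
                              seed_length, min_identity)
      if (ext$length >= min_match) {
        k <- k + 1L
        raw[[k]] <- data.frame(
          host = names(hosts)[hi],
          donor_family = dfam[[match(seeds$reference[si], names(dseq))]],
          host_start = ext$h_start, host_end = ext$h_end,
          length = ext$length, identity = ext$identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty)
  raw <- unique(do.call(rbind, raw))
  .merge_screen_hits(raw)
}

# ungapped bidirectional extension. Scoring: match +1, mismatch
# -min_identity/(1-min_identity) (so a segment scores > 0 iff its identity
# exceeds min_identity); each direction is extended with an X-drop stop and
# trimmed back to its best-scoring endpoint, so a verbatim fragment is
# reported at (essentially) identity 1.
.extend_ungapped <- function(hc, dc, hpos, dpos, seed_len, min_identity) {
  penalty <- min_identity / (1 - min_identity)
  xdrop <- 3 * penalty + 1
  walk <- function(hi, di, step) {
    best <- 0; cur <- 0; best_k <- 0L; k <- 0L
    repeat {
      hi2 <- hi + step * (k + 1L); di2 <- di + step * (k + 1L)
      if (hi2 < 1L || hi2 > length(hc) || di2 < 1L || di2 > length(dc)) break
      cur <- cur + if (hc[hi2] == dc[di2]) 1 else -penalty
      k <- k + 1L
      if (cur > best) { best <- cur; best_k <- k }
      if (cur < best - xdrop) break
    }
    best_k
  }
  # 1-based inclusive seed bounds
  h1 <- hpos + 1L; h2 <- hpos + seed_len
  d1 <- dpos + 1L; d2 <- dpos + seed_len
  kr <- walk(h2, d2, +1L)
  kl <- walk(h1, d1, -1L)
  hs <- h1 - kl; he <- h2 + kr
  ds <- d1 - kl
  matches <- sum(hc[hs:he] == dc[ds:(ds + (he - hs))])
  list(h_start = hs - 1L, h_end = he, length = he - hs + 1L,
       identity = matches / (he - hs + 1L))
}

.merge_screen_hits <- function(raw) {
  dt <- data.table(raw)
  out <- dt[order(host_start),
            {
              s <- host_start; e <- host_end; idy <- identity
              grp <- cumsum(c(1L, as.integer(s[-1] > cummax(e[-length(e)]))))
              .SD[, .(host_start = min(host_start),
                      host_end = max(host_end),
                      identity = max(identity)),
                  by = .(grp = grp)]
            },
            by = .(host, donor_family)]
  out[, grp := NULL]
  out[, length := host_end - host_start]
  setorder(out, host, donor_family, host_start)
  as.data.frame(out[, .(host, donor_family, host_start, host_end,
                        length, identity)])
}

#' Import BLASTN tabular contamination hits
#'
#' Reads standard 12-column BLAST tabular output (`-outfmt 6`: query,
#' subject, identity, length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore) and keeps hits at or below the E-value
#' cutoff (default 1e-20). Queries are donor exemplars and subjects host
#' elements; coordinates are converted to 0-based half-open on the host.
#'
#' @param path BLAST tabular file.
#' @param max_evalue E-value cutoff.
#' @param donor_families optional named vector mapping query ids to
#'   families (defaults to the query id).
#' @return data.frame in the layout of [contamination_screen()].
#' @export
import_blast_hits <- function(path, max_evalue = 1e-20,
                              donor_families = NULL) {
  cols <- c("query", "subject", "identity", "length", "mismatches",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  d <- read.delim(path, header = FALSE, col.names = cols,
                  stringsAsFactors = FALSE)
  d <- d[d$evalue <= max_evalue, , drop = FALSE]
  fam <- if (is.null(donor_families)) d$query else
    unname(donor_families[d$query])
  s0 <- pmin(d$sstart, d$send) - 1L
  e0 <- pmax(d$sstart, d$send)
  data.frame(host = d$subject, donor_family = fam,
             host_start = s0, host_end = e0, length = e0 - s0,
             identity = d$identity / 100, stringsAsFactors = FALSE)
}
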