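# Seeded synthetic-data generator: BindingDB-style TSVs with planted
# scaffold series, invalid rows and range-qualified rows, plus the
# ground-truth manifest that predicts every downstream count.
#
# Design notes: decorations are pure heavy-atom ADDITIONS to a scaffold
# (a substituent replaces an implicit hydrogen), so every series member's
# subgraph set contains the undecorated base's. The base is always given
# the best (lowest nM) affinity in its series, so it leads its cluster
# and members join it at high similarity. Substituent vocabulary and
# attachment rules are fixed in code, not configuration, so the
# similarity separations stay put across toolkit versions; tests assert
# the separations rather than assuming them.

# twelve mutually diverse drug-like scaffolds (~18-26 heavy atoms), each
# written with a terminal aliphatic tail up front: decorations attach at
# the chain end, where they perturb the subgraph population least, so
# series cohere tightly while distinct scaffolds stay far apart
.FIXTURE_CORES <- c(
  "CCOC(=O)c1ccc(NC(=O)c2ccco2)cc1",
  "CCN1CCN(C(=O)Nc2ccccc2)CC1",
  "CCOc1ccc2ccccc2c1CN1CCOCC1",
  "CCC(=O)Nc1ccc(S(=O)(=O)N2CCCCC2)cc1",
  "CCN(CCc1ccccc1)CCOc1ccc(Cl)cc1",
  "CCOC(=O)C1CCN(Cc2ccccc2)CC1",
  "CCc1ccc(C(=O)N2CCN(c3ncccn3)CC2)cc1",
  "CCN1C(=O)CC(N2CCOCC2)C1=O",
  "CCOc1ccc(CNC(=O)c2ccc3ccccc3c2)cc1",
  "CCOC(=O)N1CCC(Oc2ccccc2)CC1",
  "CCN(C)C(=O)c1ccc(Oc2ccccn2)cc1",
  "CCSCC(=O)Nc1ccc(-c2ccccc2)cc1"
)

# decoration vocabulary: single-atom substituents for series members;
# iodine is reserved for planted query compounds so queries never
# duplicate a reference structure
.FIXTURE_SUBS <- c("F", "Cl", "C", "O", "N", "Br")
.QUERY_SUB <- "I"

#' Specification for the synthetic fixture generator
#'
#' Generation is a pure function of the spec: the same spec yields
#' byte-identical output.
#'
#' @param n_targets number of synthetic protein targets
#' @param series_per_target scaffold series planted per target
#' @param compounds_per_series compounds per series (base + decorated)
#' @param n_invalid_smiles planted unparsable-structure rows
#' @param n_qualifier_rows planted rows with '>'-qualified affinities
#' @param affinity_range_nM c(low, high); affinities drawn log-uniformly
#' @param seed integer seed
#' @export
fixtureSpec <- function(n_targets = 4, series_per_target = 3,
                        compounds_per_series = 5, n_invalid_smiles = 5,
                        n_qualifier_rows = 5,
                        affinity_range_nM = c(1, 10000), seed = 7L) {
  stopifnot(n_targets >= 0, series_per_target >= 0,
            compounds_per_series >= 0, n_invalid_smiles >= 0,
            n_qualifier_rows >= 0,
            affinity_range_nM[1] > 0,
            affinity_range_nM[1] < affinity_range_nM[2])
  n_series <- n_targets * series_per_target
  if (n_series > length(.FIXTURE_CORES))
    stop(sprintf("at most %d series supported (%d scaffolds shipped)",
                 length(.FIXTURE_CORES), length(.FIXTURE_CORES)), call. = FALSE)
  list(n_targets = n_targets, series_per_target = series_per_target,
       compounds_per_series = compounds_per_series,
       n_invalid_smiles = n_invalid_smiles,
       n_qualifier_rows = n_qualifier_rows,
       affinity_range_nM = affinity_range_nM, seed = as.integer(seed))
}

# run fn with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

# insertion points: single-letter carbon atoms (not Cl/Br, not bracket
# atoms, not already-branched positions), after any ring-closure digits.
# Terminal-chain carbons (string-initial, branch-terminal or
# string-final aliphatic C) are listed first: attaching there perturbs
# the fingerprint least, which keeps series internally tight.
.decorationPoints <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  pts <- integer(0); terminal <- logical(0)
  in_bracket <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "[") { in_bracket <- TRUE; next }
    if (ch == "]") { in_bracket <- FALSE; next }
    if (in_bracket) next
    if (ch != "c" && ch != "C") next
    nxt <- if (i < length(chars)) chars[i + 1] else ""
    if (nxt == "l" || nxt == "r") next          # Cl / Br (Cr not used)
    j <- i
    while (j < length(chars) && grepl("[0-9]", chars[j + 1])) j <- j + 1
    after <- if (j < length(chars)) chars[j + 1] else ""
    if (after == "(") next                       # keep one branch per site
    prev <- if (i > 1) chars[i - 1] else ""
    is_term <- ch == "C" &&
      (i == 1 || prev == "(" || j == length(chars))
    pts <- c(pts, j); terminal <- c(terminal, is_term)
  }
  pts[order(!terminal, seq_along(pts))]
}

.insertAt <- function(smiles, pos, sub) {
  paste0(substr(smiles, 1, pos), "(", sub, ")",
         substr(smiles, pos + 1, nchar(smiles)))
}

#' Generate a scaffold series by decorating a core
#'
#' The first member is the core itself; the rest carry one small
#' substituent (halogen, methyl, hydroxy, amino) at an enumerable ring
#' position. All members are validated and pairwise distinct as
#' canonical structures; because decorations only add heavy atoms, every
#' member stays highly similar to the core.
#'
#' @param core_smiles scaffold SMILES
#' @param n series size (n = 1 returns just the core)
#' @param seed seed controlling which decorations are picked
#' @param subs substituent vocabulary (fixed default)
#' @return character vector of n SMILES
#' @export
makeScaffoldSeries <- function(core_smiles, n, seed = 1L,
                               subs = .FIXTURE_SUBS) {
  stopifnot(n >= 1)
  core_can <- canonicalSmiles(core_smiles)
  if (is.na(core_can))
    stop(sprintf("core does not parse: %s", core_smiles), call. = FALSE)
  if (n == 1) return(core_smiles)
  pts <- .decorationPoints(core_smiles)
  if (!length(pts))
    stop(sprintf("core has no substitutable position: %s", core_smiles),
         call. = FALSE)
  # position-major: exhaust the preferred (chain-terminal) site before
  # moving on; the seed shuffles the substituent order at each site
  sub_ord <- .withSeed(seed, function() sample(subs))
  cand <- expand.grid(sub = sub_ord, pos = pts, stringsAsFactors = FALSE)
  ord <- seq_len(nrow(cand))
  out <- core_smiles
  seen <- core_can
  for (k in ord) {
    if (length(out) == n) break
    s <- .insertAt(core_smiles, cand$pos[k], cand$sub[k])
    can <- canonicalSmiles(s)
    if (is.na(can) || can %in% seen) next
    ok <- tryCatch({ molFromSmiles(s); TRUE }, error = function(e) FALSE)
    if (!ok) next
    out <- c(out, s)
    seen <- c(seen, can)
  }
  if (length(out) < n)
    stop(sprintf("could not generate %d distinct decorations of %s",
                 n - 1, core_smiles), call. = FALSE)
  out
}

# internal: plant all series for a spec; returns data.frame with
# target/series bookkeeping
.plantSeries <- function(spec) {
  n_series <- spec$n_targets * spec$series_per_target
  rows <- list()
  for (si in seq_len(n_series)) {
    target_i <- ((si - 1) %/% spec$series_per_target) + 1
    series <- makeScaffoldSeries(.FIXTURE_CORES[si],
                                 spec$compounds_per_series,
                                 seed = spec$seed + si)
    rows[[si]] <- data.frame(
      smiles = series,
      target = target_i,
      series = si,
      member = seq_along(series),
      is_base = seq_along(series) == 1,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.targetUniprot <- function(i) sprintf("P1%04d", i)
.targetName <- function(i) sprintf("Synthetic target %d", i)

#' Generate a synthetic bioactivity TSV with ground truth
#'
#' Emits a TSV in the default column dialect containing the planted
#' scaffold series plus the requested numbers of unparsable-SMILES rows
#' and range-qualified rows, together with a manifest that predicts the
#' post-filter row count, per-target group sizes, the cluster count at
#' the generator's separation threshold, and a planted query compound
#' (with its intended target) per target.
#'
#' @param spec a \code{\link{fixtureSpec}}
#' @param path output TSV path
#' @return list(path, manifest); the manifest has components \code{rows}
#'   (per-row ground truth), \code{expected} (predicted pipeline counts)
#'   and \code{queries} (planted query compounds)
#' @export
makeSyntheticTsv <- function(spec = fixtureSpec(), path = tempfile(fileext = ".tsv")) {
  planted <- if (spec$n_targets * spec$series_per_target *
                 spec$compounds_per_series > 0) .plantSeries(spec)
             else data.frame(smiles = character(), target = integer(),
                             series = integer(), member = integer(),
                             is_base = logical(), stringsAsFactors = FALSE)
  n_planted <- nrow(planted)
  # affinities: log-uniform; the series base always gets the series
  # minimum so it anchors its cluster and wins representative selection
  aff <- .withSeed(spec$seed * 1000 + 1, function() {
    lo <- log(spec$affinity_range_nM[1]); hi <- log(spec$affinity_range_nM[2])
    exp(stats::runif(n_planted, lo, hi))
  })
  if (n_planted) {
    aff <- unlist(lapply(split(aff, factor(planted$series,
                                           levels = unique(planted$series))),
                         function(a) {
      a_sorted <- sort(a)
      c(a_sorted[1], a_sorted[-1])
    }), use.names = FALSE)
    planted$affinity_nM <- round(aff, 3)
    planted$affinity_type <- ifelse(seq_len(n_planted) %% 2 == 1, "Ki", "IC50")
  } else {
    planted$affinity_nM <- numeric(0)
    planted$affinity_type <- character(0)
  }

  qualifier <- if (spec$n_qualifier_rows > 0) {
    src <- planted[rep_len(which(planted$is_base), spec$n_qualifier_rows), ,
                   drop = FALSE]
    data.frame(smiles = src$smiles, target = src$target, series = NA_integer_,
               role = "qualifier",
               affinity_text = paste0(">", spec$affinity_range_nM[2]),
               affinity_type = "Ki", stringsAsFactors = FALSE)
  } else NULL
  invalid <- if (spec$n_invalid_smiles > 0) {
    data.frame(smiles = sprintf("%%BAD_STRUCTURE_%d%%",
                                seq_len(spec$n_invalid_smiles)),
               target = rep_len(seq_len(max(spec$n_targets, 1)),
                                spec$n_invalid_smiles),
               series = NA_integer_, role = "invalid",
               affinity_text = "100", affinity_type = "IC50",
               stringsAsFactors = FALSE)
  } else NULL

  all_rows <- rbind(
    if (n_planted) data.frame(
      smiles = planted$smiles, target = planted$target,
      series = planted$series, role = "valid",
      affinity_text = sprintf("%.3f", planted$affinity_nM),
      affinity_type = planted$affinity_type, stringsAsFactors = FALSE),
    qualifier, invalid)
  if (is.null(all_rows))
    all_rows <- data.frame(smiles = character(), target = integer(),
                           series = integer(), role = character(),
                           affinity_text = character(),
                           affinity_type = character(), stringsAsFactors = FALSE)
  n <- nrow(all_rows)
  all_rows$monomer_id <- sprintf("M%05d", seq_len(n))

  d <- defaultDialect()
  header <- c(d$smiles, d$monomer_id, d$target_name, d$uniprot, d$ki, d$ic50)
  lines <- c(paste(header, collapse = "\t"),
             vapply(seq_len(n), function(i) {
               r <- all_rows[i, ]
               paste(c(r$smiles, r$monomer_id, .targetName(r$target),
                       .targetUniprot(r$target),
                       if (r$affinity_type == "Ki") r$affinity_text else "",
                       if (r$affinity_type == "IC50") r$affinity_text else ""),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)

  queries <- if (spec$n_targets > 0 && n_planted > 0) {
    do.call(rbind, lapply(seq_len(spec$n_targets), function(t) {
      first_series <- (t - 1) * spec$series_per_target + 1
      q <- .insertAt(.FIXTURE_CORES[first_series],
                     .decorationPoints(.FIXTURE_CORES[first_series])[1],
                     .QUERY_SUB)
      data.frame(query_smiles = q, expected_target = .targetUniprot(t),
                 expected_target_name = .targetName(t),
                 in_series = first_series, stringsAsFactors = FALSE)
    }))
  } else NULL

  manifest <- list(
    spec = spec,
    rows = all_rows,
    expected = list(
      n_raw = n,
      n_after_measurement_filter = n - spec$n_qualifier_rows,
      n_after_sanitize = n - spec$n_qualifier_rows - spec$n_invalid_smiles,
      group_sizes = if (n_planted) table(planted$target),
      n_clusters_at_0.8 = spec$n_targets * spec$series_per_target),
    queries = queries)
  list(path = path, manifest = manifest)
}

#' Generate a labeled compound-pair panel for metric selection
#'
#' Builds the planted scaffold series for the spec and emits every
#' within-series pair plus an equal-sized seeded sample of cross-series
#' pairs, labeled. This panel is the offline stand-in for a large
#' receptor-ligand pair collection when calibrating the correlation
#' filter.
#'
#' @param spec a \code{\link{fixtureSpec}}
#' @return data.frame with columns smiles_a, smiles_b, label
#'   ("within" / "cross"), series_a, series_b
#' @export
makePairPanel <- function(spec = fixtureSpec()) {
  planted <- .plantSeries(spec)
  within <- do.call(rbind, lapply(split(seq_len(nrow(planted)),
                                        planted$series), function(g) {
    if (length(g) < 2) return(NULL)
    cmb <- utils::combn(g, 2)
    data.frame(i = cmb[1, ], j = cmb[2, ], label = "within",
               stringsAsFactors = FALSE)
  }))
  cross_all <- utils::combn(nrow(planted), 2)
  cross_all <- cross_all[, planted$series[cross_all[1, ]] !=
                           planted$series[cross_all[2, ]], drop = FALSE]
  n_cross <- min(ncol(cross_all), nrow(within))
  pick <- .withSeed(spec$seed * 1000 + 2,
                    function() sample.int(ncol(cross_all), n_cross))
  cross <- data.frame(i = cross_all[1, pick], j = cross_all[2, pick],
                      label = "cross", stringsAsFactors = FALSE)
  pairs <- rbind(within, cross)
  data.frame(smiles_a = planted$smiles[pairs$i],
             smiles_b = planted$smiles[pairs$j],
             label = pairs$label,
             series_a = planted$series[pairs$i],
             series_b = planted$series[pairs$j],
             stringsAsFactors = FALSE)
}
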