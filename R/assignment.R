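#' Sparsify a connectivity map to its top fraction
#'
#' Keeps the `k = max(1, floor(fraction * n_defined))` defined vertices with
#' the highest signed partial correlation (the top-1% rule by default) and
#' binarizes: 1 on kept vertices, 0 elsewhere. Ties at the cutoff are broken
#' by the lower vertex index. Undefined (`NA`) vertices never compete.
#'
#' @param conn A `connectivity_map` (or numeric vector, `NA` = undefined).
#' @param fraction Fraction of defined vertices to keep (default 0.01).
#' @param use_abs Rank by |r| instead of signed r (default `FALSE`; the
#'   signed-value ranking is the primary definition, the absolute-value
#'   variant a robustness flag).
#' @return Integer 0/1 vector over all vertices.
#' @export
sparsify <- function(conn, fraction = 0.01, use_abs = FALSE) {
  r <- as.numeric(conn)
  defined <- which(!is.na(r))
  if (length(defined) == 0) stop_input("all vertices undefined (degenerate)")
  k <- max(1L, floor(fraction * length(defined)))
  key <- if (use_abs) abs(r[defined]) else r[defined]
  kept <- defined[order(-key, defined)][seq_len(k)]
  out <- integer(length(r))
  out[kept] <- 1L
  out
}

#' Per-network overlap profile of a binarized map
#'
#' For each network n in 1..7, the percentage of kept (suprathreshold)
#' vertices carrying label n; label-0 vertices contribute to the unassigned
#' share. Network percentages plus the unassigned share always sum to 100.
#'
#' @param binary_map Integer 0/1 per-vertex vector (see [sparsify()]).
#' @param parcellation A `parcellation_map` of the same length.
#' @param metric `"percent"` (default; denominator = kept-vertex count, so
#'   network shares plus the unassigned share sum to 100) or `"dice"`
#'   (2 |kept n network| / (|kept| + |network|) x 100, a robustness
#'   alternative whose values do not sum to 100).
#' @return List of class `overlap_profile` with `overlap` (named length-7
#'   percentages), `unassigned` (percentage) and `n_kept`.
#' @export
overlap_profile <- function(binary_map, parcellation,
                            metric = c("percent", "dice")) {
  metric <- match.arg(metric)
  labels <- as.integer(unclass(parcellation))
  if (length(binary_map) != length(labels))
    stop_input("map and parcellation are not on the same mesh")
  kept <- labels[binary_map != 0]
  if (length(kept) == 0) stop_input("empty kept set (degenerate)")
  counts <- tabulate(kept + 1L, nbins = 8L)   # slot 1 = label 0
  if (metric == "percent") {
    net <- 100 * counts[2:8] / length(kept)
  } else {
    sizes <- tabulate(labels + 1L, nbins = 8L)
    net <- 200 * counts[2:8] / (length(kept) + sizes[2:8])
    net[!is.finite(net)] <- 0
  }
  structure(list(
    overlap = stats::setNames(net, yeo7_abbrev),
    unassigned = 100 * counts[1] / length(kept),
    n_kept = length(kept)
  ), class = "overlap_profile")
}

#' Assign the targeted network from an overlap profile
#'
#' Argmax over networks 1..7 (the unassigned share never wins). Exact ties
#' are broken by the lowest network index and flagged; a profile with all
#' network overlaps zero yields `NA` with the `none` flag rather than an
#' error.
#'
#' @param profile An [overlap_profile()].
#' @return List with `network` (integer code or `NA`), `name`
#'   (abbreviation), `tie` and `none` logical flags.
#' @export
assign_network <- function(profile) {
  stopifnot(inherits(profile, "overlap_profile"))
  ov <- profile$overlap
  if (all(ov == 0))
    return(list(network = NA_integer_, name = NA_character_,
                tie = FALSE, none = TRUE))
  m <- max(ov)
  winners <- which(ov == m)
  list(network = as.integer(winners[1]), name = yeo7_abbrev[winners[1]],
       tie = length(winners) > 1, none = FALSE)
}

#' Map a grid location to its 3 x 3 zone
#'
#' The 36 coil locations are grouped into nine zones Z1-Z9 of 2 x 2
#' locations each: `zone = 3 * floor(row / 2) + floor(col / 2) + 1`. With
#' row 0 anterior and column 0 medial, Z1 is the medial-anterior corner,
#' Z3 lateral-anterior, Z7 medial-posterior and Z9 lateral-posterior; the
#' medial zone column is Z1/Z4/Z7 and the lateral column Z3/Z6/Z9.
#'
#' @param row,col Integer grid indices in 0..5 (vectorized).
#' @return Integer zone index 1..9.
#' @export
zone_of <- function(row, col) {
  if (any(row < 0 | row > 5 | col < 0 | col > 5))
    stop_input("row and col must be in 0..5")
  as.integer(3 * (row %/% 2) + col %/% 2 + 1)
}

#' Map a coil orientation to its 45-degree window
#'
#' Orientations are reduced to four 45-degree windows to absorb incidental
#' stimulation: W1 = \{0, 15, 30\}, W2 = \{45, 60, 75\},
#' W3 = \{90, 105, 120\}, W4 = \{135, 150, 165\} (half-open bins
#' \[0, 45), ..., \[135, 180)).
#'
#' @param theta Orientation in degrees, one of `seq(0, 165, by = 15)`
#'   (vectorized).
#' @return Integer window index 1..4.
#' @export
orientation_window <- function(theta) {
  if (any(!(theta %in% seq(0, 165, by = 15))))
    stop_input("theta must be one of 0, 15, ..., 165 degrees")
  as.integer(theta %/% 45 + 1)
}

#' Assign networks for a table of configurations
#'
#' Convenience wrapper running [sparsify()], [overlap_profile()] and
#' [assign_network()] for each connectivity map and attaching zone and
#' orientation-window labels.
#'
#' @param conn_maps List of `connectivity_map`s, one per placement.
#' @param placements The matching `coil_grid` rows.
#' @param parcellation A `parcellation_map`.
#' @param sparsity Top fraction kept (default 0.01).
#' @param use_abs Rank by absolute value (default `FALSE`).
#' @param metric Overlap metric passed to [overlap_profile()].
#' @return A `targeting_result` data frame: one row per configuration with
#'   `row`, `col`, `theta_deg`, `zone`, `window`, the seven overlap
#'   percentages (`ov_VIS` .. `ov_DN`), `unassigned`, `n_kept`,
#'   `network` (code), `network_name`, `tie`.
#' @export
assign_targets <- function(conn_maps, placements, parcellation,
                           sparsity = 0.01, use_abs = FALSE,
                           metric = "percent") {
  if (length(conn_maps) != nrow(placements))
    stop_input("one connectivity map per placement required")
  rows <- lapply(seq_along(conn_maps), function(i) {
    bin <- sparsify(conn_maps[[i]], sparsity, use_abs)
    prof <- overlap_profile(bin, parcellation, metric)
    asg <- assign_network(prof)
    p <- placements[i, ]
    cbind(
      data.frame(row = p$row, col = p$col, theta_deg = p$theta_deg,
                 zone = zone_of(p$row, p$col),
                 window = orientation_window(p$theta_deg)),
      stats::setNames(as.data.frame(as.list(prof$overlap)),
                      paste0("ov_", yeo7_abbrev)),
      data.frame(unassigned = prof$unassigned, n_kept = prof$n_kept,
                 network = asg$network,
                 network_name = ifelse(asg$none, NA, asg$name),
                 tie = asg$tie)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("targeting_result", class(out))
  out
}

#' Summarize targeting results over zones and orientation windows
#'
#' Group-level aggregation: overall stimulation frequency per network
#' (percentage of configurations assigning it), per-zone frequency tables
#' with the modal network (ties reported as all tied networks, joined by
#' `"/"`), and per-zone-per-window modal networks.
#'
#' @param results A `targeting_result` data frame (see [assign_targets()]).
#' @return List of class `targeting_summary` with `overall` (network,
#'   n, percent), `by_zone` and `by_zone_window` data frames.
#' @export
summarize_targeting <- function(results) {
  if (is.null(results) || nrow(results) == 0)
    stop_input("empty results table")
  n_total <- nrow(results)
  asg <- factor(results$network_name, levels = yeo7_abbrev)
  overall <- data.frame(network = yeo7_abbrev,
                        n = as.integer(table(asg)))
  overall$percent <- 100 * overall$n / n_total

  modal <- function(sub) {
    tab <- table(factor(sub$network_name, levels = yeo7_abbrev))
    tab <- tab[tab > 0]
    if (length(tab) == 0) return(list(name = NA_character_, n = 0L, tie = FALSE))
    mx <- max(tab)
    winners <- names(tab)[tab == mx]
    list(name = paste(winners, collapse = "/"), n = as.integer(mx),
         tie = length(winners) > 1)
  }
  by_zone <- do.call(rbind, lapply(sort(unique(results$zone)), function(z) {
    sub <- results[results$zone == z, ]
    m <- modal(sub)
    data.frame(zone = z, n_configs = nrow(sub), modal_network = m$name,
               modal_n = m$n, tie = m$tie)
  }))
  combos <- unique(results[, c("zone", "window")])
  combos <- combos[order(combos$zone, combos$window), ]
  by_zw <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    z <- combos$zone[i]; w <- combos$window[i]
    sub <- results[results$zone == z & results$window == w, ]
    m <- modal(sub)
    data.frame(zone = z, window = w, n_configs = nrow(sub),
               modal_network = m$name, modal_n = m$n, tie = m$tie)
  }))
  structure(list(overall = overall, by_zone = by_zone,
                 by_zone_window = by_zw, n_total = n_total),
            class = "targeting_summary")
}

#' @export
print.targeting_summary <- function(x, ...) {
  cat(sprintf("Targeting summary over %d configurations\n", x$n_total))
  cat("Overall stimulation frequency (%):\n")
  print(x$overall, row.names = FALSE)
  cat("Modal network per zone:\n")
  print(x$by_zone, row.names = FALSE)
  invisible(x)
}
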