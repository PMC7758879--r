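#' Build a food-leaving event log
#'
#' Per-minute counts of worms present at the start of the minute and
#' worms scoring a leaving event (whole body off the food patch with no
#' immediate retraction) during that minute. Leaving is treated as
#' absorbing within the observation window; an optional `returns` vector
#' allows worms to re-enter for generality.
#'
#' @param leavers Integer vector, one entry per minute.
#' @param n_worms Worms on the patch at the start of minute 1.
#' @param returns Optional integer vector of worms returning each minute
#'   (credited at the start of the next minute); default none.
#' @param timepoint_h Assay timepoint in hours (e.g. 0, 3, 6, 9);
#'   optional metadata.
#' @return A data.frame of class `leaving_log` with columns `minute`,
#'   `worms_at_start`, `leavers` (and `returns` when supplied).
#' @export
leaving_log <- function(leavers, n_worms, returns = NULL,
                        timepoint_h = NA_real_) {
  leavers <- as.integer(leavers)
  duration <- length(leavers)
  if (duration == 0) stop("log must cover at least one minute")
  if (is.null(returns)) returns <- integer(duration)
  returns <- as.integer(returns)
  if (length(returns) != duration) {
    stop("returns must have one entry per minute")
  }
  worms <- integer(duration)
  w <- as.integer(n_worms)
  for (m in seq_len(duration)) {
    worms[m] <- w
    if (leavers[m] < 0 || leavers[m] > w) {
      stop("minute ", m, ": leavers (", leavers[m],
           ") outside [0, worms at start = ", w, "]")
    }
    w <- w - leavers[m] + returns[m]
  }
  out <- data.frame(minute = seq_len(duration), worms_at_start = worms,
                    leavers = leavers)
  if (any(returns != 0)) out$returns <- returns
  attr(out, "timepoint_h") <- timepoint_h
  class(out) <- c("leaving_log", "data.frame")
  out
}

#' Food-leaving probability of an assay
#'
#' The per-minute leaving probability: number of worms leaving in a
#' minute divided by the number of worms on the patch at the start of
#' that minute, averaged over the observation window. Minutes with zero
#' worms at the start are excluded from the average (the ratio is
#' undefined there), which keeps assays with early full departure
#' well-defined.
#'
#' @param log A [leaving_log()].
#' @return The mean per-minute leaving probability.
#' @export
leaving_probability <- function(log) {
  valid <- log$worms_at_start > 0
  if (!any(valid)) stop("no minute has worms at its start")
  mean(log$leavers[valid] / log$worms_at_start[valid])
}

# Default ring specification: score -> square count as declared in the
# off-food assay protocol (3x3 core = 9, then 25, 49, 81, 121).
default_ring_spec <- function() {
  data.frame(score = 1:5, declared_count = c(9, 25, 49, 81, 121))
}

#' Build an exploration grid
#'
#' A boolean occupancy mask over a plate divided into square cells
#' (default 0.5 cm sides, 0.25 cm^2), with the food patch at a given
#' cell. For off-food assays occupancy marks bacterial growth seeded by
#' the worm's excursions; for on-food assays it marks squares crossed by
#' trails in the lawn. Partial edge squares are treated as whole squares.
#'
#' @param occupancy Logical (or 0/1) matrix.
#' @param patch_center `c(row, col)` of the food patch square; defaults
#'   to the central square.
#' @param square_side Side of one square in cm; default 0.5.
#' @param ring_spec Data.frame (`score`, `declared_count`) of ring scores;
#'   defaults to scores 1..5 with declared counts 9, 25, 49, 81, 121.
#' @return An object of class `exploration_grid`.
#' @export
exploration_grid <- function(occupancy,
                             patch_center = ceiling(dim(occupancy) / 2),
                             square_side = 0.5,
                             ring_spec = default_ring_spec()) {
  occupancy <- as.matrix(occupancy)
  if (length(occupancy) == 0) stop("occupancy grid has zero squares")
  mode(occupancy) <- "logical"
  if (anyNA(occupancy)) stop("occupancy must be TRUE/FALSE (or 0/1)")
  patch_center <- as.integer(patch_center)
  if (length(patch_center) != 2 ||
      patch_center[1] < 1 || patch_center[1] > nrow(occupancy) ||
      patch_center[2] < 1 || patch_center[2] > ncol(occupancy)) {
    stop("patch_center must be a (row, col) pair on the plate")
  }
  if (is.unsorted(ring_spec$score, strictly = TRUE)) {
    stop("ring scores must be strictly increasing")
  }
  structure(list(occupancy = occupancy, patch_center = patch_center,
                 square_side = square_side, ring_spec = ring_spec),
            class = "exploration_grid")
}

#' Ring score of a grid square
#'
#' Assigns the concentric ring score of a square relative to the food
#' patch. Under the default `"chebyshev"` geometry, score k is the index
#' of the smallest centered odd square containing the cell (3x3 -> 1,
#' 5x5 -> 2, ..., 11x11 -> 5): the ring shells hold 9, 16, 24, 32 and 40
#' squares. The `"literal"` geometry instead fills rings with exactly the
#' declared square counts (9, 25, 49, 81, 121 by default) in order of
#' proximity — Chebyshev distance first, then squared Euclidean distance,
#' then row/column for determinism — so a declared ring may reach into
#' the next Chebyshev shell. In both geometries squares beyond the last
#' ring take the maximum score.
#'
#' @param square `c(row, col)` of the square.
#' @param patch_center `c(row, col)` of the food patch square.
#' @param ring_spec Ring specification (see [exploration_grid()]).
#' @param geometry `"chebyshev"` (default) or `"literal"`.
#' @return The integer ring score.
#' @export
ring_of_square <- function(square, patch_center,
                           ring_spec = default_ring_spec(),
                           geometry = c("chebyshev", "literal")) {
  geometry <- match.arg(geometry)
  scores <- ring_spec$score
  dx <- square[1] - patch_center[1]
  dy <- square[2] - patch_center[2]
  d <- max(abs(dx), abs(dy))
  if (geometry == "chebyshev") {
    k <- min(max(d, 1L), length(scores))
    return(scores[k])
  }
  # literal geometry: rank the square within the proximity ordering of the
  # infinite grid and map the rank through cumulative declared counts
  cum <- cumsum(ring_spec$declared_count)
  if (d == 0) return(scores[1])
  shell_before <- (2 * d - 1)^2  # squares with Chebyshev distance < d
  shell <- shell_cells(d)
  pos <- which(shell$dx == dx & shell$dy == dy)
  rank <- shell_before + pos
  k <- findInterval(rank - 1, cum) + 1L
  scores[min(k, length(scores))]
}

# Cells of the Chebyshev shell at distance d, in proximity order
# (squared Euclidean distance, then dx, then dy).
shell_cells <- function(d) {
  dx <- rep(-d:d, times = 2 * d + 1)
  dy <- rep(-d:d, each = 2 * d + 1)
  on <- pmax(abs(dx), abs(dy)) == d
  dx <- dx[on]; dy <- dy[on]
  o <- order(dx^2 + dy^2, dx, dy)
  list(dx = dx[o], dy = dy[o])
}

#' Off-food exploration score
#'
#' Scores every occupied square outside the food patch by its ring score
#' and aggregates. The patch square itself is excluded: occupancy there
#' reflects the seeded lawn, not exploration.
#'
#' @param grid An [exploration_grid()].
#' @param aggregation `"sum"` (default), `"max"` or `"mean"` over the
#'   per-square scores.
#' @param geometry Passed to [ring_of_square()].
#' @return An object of class `exploration_score`: a list with
#'   `per_square_scores` (data.frame row, col, score), `total`,
#'   `aggregation` and `geometry`.
#' @export
off_food_score <- function(grid, aggregation = c("sum", "max", "mean"),
                           geometry = c("chebyshev", "literal")) {
  aggregation <- match.arg(aggregation)
  geometry <- match.arg(geometry)
  occ <- which(grid$occupancy, arr.ind = TRUE)
  occ <- occ[!(occ[, 1] == grid$patch_center[1] &
                 occ[, 2] == grid$patch_center[2]), , drop = FALSE]
  if (nrow(occ) == 0) {
    warning("no occupied squares outside the food patch; score 0")
    scores <- data.frame(row = integer(), col = integer(),
                         score = integer())
    total <- 0
  } else {
    sc <- vapply(seq_len(nrow(occ)), function(i) {
      ring_of_square(occ[i, ], grid$patch_center, grid$ring_spec, geometry)
    }, numeric(1))
    scores <- data.frame(row = occ[, 1], col = occ[, 2], score = sc,
                         row.names = NULL)
    total <- switch(aggregation, sum = sum(sc), max = max(sc),
                    mean = mean(sc))
  }
  structure(list(per_square_scores = scores, total = total,
                 aggregation = aggregation, geometry = geometry),
            class = "exploration_score")
}

#' @export
print.exploration_score <- function(x, ...) {
  cat("<exploration_score> total", x$total, "(", x$aggregation, ",",
      x$geometry, "geometry,", nrow(x$per_square_scores),
      "scored squares )\n")
  invisible(x)
}

#' On-food exploration coverage
#'
#' Percentage of plate grid squares crossed by the worm's trails.
#'
#' @param grid An [exploration_grid()].
#' @return Coverage percent in \[0, 100\].
#' @export
on_food_coverage <- function(grid) {
  100 * sum(grid$occupancy) / length(grid$occupancy)
}

#' Read a leaving-log table
#'
#' Tab-separated file with columns `minute`, `worms_at_start`, `leavers`
#' and optionally `assay_id`, `genotype`, `timepoint_h`, `returns`; one
#' block of rows per (assay_id, timepoint_h).
#'
#' @param path Input path.
#' @return A list of [leaving_log()] objects, named by assay (and
#'   timepoint when present), each carrying `assay_id`, `genotype` and
#'   `timepoint_h` attributes.
#' @export
read_leaving_logs <- function(path) {
  if (!file.exists(path)) stop("leaving-log file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("minute", "worms_at_start", "leavers")
  if (!all(need %in% names(tab))) {
    stop("leaving-log file '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  if (!"assay_id" %in% names(tab)) tab$assay_id <- "assay1"
  if (!"timepoint_h" %in% names(tab)) tab$timepoint_h <- NA_real_
  if (!"genotype" %in% names(tab)) tab$genotype <- NA_character_
  key <- paste(tab$assay_id, tab$timepoint_h, sep = "@")
  lapply(split(tab, key), function(block) {
    block <- block[order(block$minute), , drop = FALSE]
    bad <- which(block$leavers > block$worms_at_start |
                   block$leavers < 0)
    if (length(bad) > 0) {
      stop("assay '", block$assay_id[1], "': leavers exceed worms at ",
           "start in minute(s) ", paste(block$minute[bad], collapse = ", "))
    }
    log <- data.frame(minute = block$minute,
                      worms_at_start = block$worms_at_start,
                      leavers = block$leavers)
    if ("returns" %in% names(block)) log$returns <- block$returns
    attr(log, "assay_id") <- block$assay_id[1]
    attr(log, "genotype") <- block$genotype[1]
    attr(log, "timepoint_h") <- block$timepoint_h[1]
    class(log) <- c("leaving_log", "data.frame")
    log
  })
}

#' Read an exploration grid occupancy mask
#'
#' Tab-separated 0/1 matrix, one plate row per line, no header.
#'
#' @param path Input path.
#' @param ... Passed to [exploration_grid()] (`patch_center`, ...).
#' @return An [exploration_grid()].
#' @export
read_grid <- function(path, ...) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  exploration_grid(m, ...)
}
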