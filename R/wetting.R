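# Per-water tracking through the gate region, wetted/de-wetted state
# classification, and sub-cavity occupancy statistics.

# Boundary-crossing events for one molecule's (time, coordinate) series.
# Crossing times are linearly interpolated between consecutive frames.
.crossingEvents <- function(tm, x, lo, hi, frameIdx) {
  n <- length(x)
  if (n < 2L) return(data.frame(time = numeric(0), type = character(0),
                                side = numeric(0)))
  inside <- x >= lo & x <= hi
  ev <- list(); k <- 0L
  for (i in seq_len(n - 1L)) {
    if (frameIdx[i + 1L] - frameIdx[i] != 1L) next   # non-adjacent frames
    a <- x[i]; b <- x[i + 1L]
    if (inside[i] == inside[i + 1L]) next
    if (!inside[i] && inside[i + 1L]) {              # entry
      bound <- if (a < lo) lo else hi
      side <- if (a < lo) -1 else 1
      type <- "entry"
    } else {                                         # exit
      bound <- if (b < lo) lo else hi
      side <- if (b < lo) -1 else 1
      type <- "exit"
    }
    tc <- tm[i] + (bound - a) / (b - a) * (tm[i + 1L] - tm[i])
    k <- k + 1L
    ev[[k]] <- data.frame(time = tc, type = type, side = side)
  }
  if (!k) return(data.frame(time = numeric(0), type = character(0),
                            side = numeric(0)))
  do.call(rbind, ev)
}

#' Track individual water molecules through a pathway region
#'
#' Builds one \linkS4class{WaterTrack} per molecule that ever enters the
#' given s interval: the in-region time series of its pathway coordinate,
#' plus entry/exit events whose times are obtained by linear interpolation
#' of the boundary crossing between frames. The exit side is the sign of
#' the crossed boundary (+1 = upper-s boundary, -1 = lower-s boundary);
#' because z = -s, the +s side is the lower-z side.
#'
#' @param traj a \linkS4class{Trajectory} with persistent molecule ids.
#' @param region numeric length-2 s interval (nm) within the pathway range.
#' @param pathway a \linkS4class{Pathway}.
#' @param radialCutoffFactor passed to \code{\link{mapToPathway}}.
#' @param coordinate track in "s" (default) or in "z" (mirror image,
#'   z = -s, with \code{region} then interpreted in z).
#' @return list of \linkS4class{WaterTrack} objects, named by molecule id.
#' @export
trackWaters <- function(traj, region, pathway, radialCutoffFactor = 1.2,
                        coordinate = c("s", "z")) {
  stopifnot(is(traj, "Trajectory"), length(region) == 2)
  coordinate <- match.arg(coordinate)
  if (!traj@persistentIds)
    stop("molecule ids are not persistent across frames; tracking needs a stable id map")
  region <- sort(region)
  prange <- range(pathway@s)
  chk <- if (coordinate == "s") region else sort(-region)
  if (chk[1] < prange[1] - 1e-9 || chk[2] > prange[2] + 1e-9)
    stop("region must lie within the pathway s range")

  mapped <- mapToPathway(traj, pathway, radialCutoffFactor)
  if (!nrow(mapped)) return(list())
  mapped$coordValue <- if (coordinate == "z") -mapped$s else mapped$s
  lo <- region[1]; hi <- region[2]

  ord <- order(mapped$molId, mapped$frame)
  mapped <- mapped[ord, , drop = FALSE]
  byId <- split(mapped, mapped$molId)

  tracks <- list()
  for (d in byId) {
    x <- d$coordValue
    inside <- x >= lo & x <= hi
    if (!any(inside)) next
    ev <- .crossingEvents(d$time, x, lo, hi, d$frame)
    tr <- new("WaterTrack", molId = as.integer(d$molId[1]),
              time = d$time[inside], s = x[inside],
              events = ev, region = region)
    tracks[[as.character(d$molId[1])]] <- tr
  }
  tracks
}

#' Classify per-frame wetted/de-wetted states of the gate
#'
#' A frame is wetted iff its gate occupancy is at least \code{threshold}
#' waters (default 1: in a gate holding only ~1-4 waters a single molecule
#' already constitutes partial hydration). Dwell times are the durations
#' of maximal runs of each state.
#'
#' @param occupancy numeric per-frame gate water counts, or the data.frame
#'   returned by \code{\link{gateOccupancy}}.
#' @param threshold occupancy defining the wetted state (>= 1).
#' @param times frame times in ns (taken from \code{occupancy} when it is
#'   a data.frame); regular spacing is assumed for dwell durations.
#' @return a \linkS4class{WettingSeries}.
#' @examples
#' ws <- classifyWetting(c(2, 2, 0, 0, 2, 2), threshold = 1,
#'                       times = 0:5)
#' dwellTimes(ws, "wet")
#' @export
classifyWetting <- function(occupancy, threshold = 1, times = NULL) {
  if (is.data.frame(occupancy)) {
    times <- occupancy$time
    occupancy <- occupancy$count
  }
  if (!length(occupancy)) stop("empty occupancy series")
  if (threshold < 1) stop("threshold must be >= 1")
  if (is.null(times)) times <- seq_along(occupancy) - 1
  if (length(times) != length(occupancy))
    stop("times and occupancy must have equal length")
  dt <- if (length(times) > 1L) times[2] - times[1] else 1
  wet <- occupancy >= threshold
  r <- rle(wet)
  dwell <- r$lengths * dt
  new("WettingSeries", time = as.numeric(times),
      occupancy = as.numeric(occupancy), wetted = wet,
      threshold = threshold, wettedFraction = mean(wet),
      dwellWet = dwell[r$values], dwellDry = dwell[!r$values],
      metadata = list(frameDt = dt))
}

#' Per-frame gate occupancy from a trajectory
#'
#' Counts, for every frame (including empty ones), the pore waters whose
#' pathway coordinate lies inside the gate region.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pathway a \linkS4class{Pathway}.
#' @param region numeric length-2 s interval (nm).
#' @param radialCutoffFactor passed to \code{\link{mapToPathway}}.
#' @return data.frame with columns \code{frame}, \code{time}, \code{count}.
#' @export
gateOccupancy <- function(traj, pathway, region, radialCutoffFactor = 1.2) {
  region <- sort(region)
  mapped <- mapToPathway(traj, pathway, radialCutoffFactor)
  frames <- attr(mapped, "frames")
  inside <- mapped$s >= region[1] & mapped$s <= region[2]
  cnt <- table(factor(mapped$frame[inside], levels = frames$frame))
  data.frame(frame = frames$frame, time = frames$time,
             count = as.integer(cnt))
}

#' Sub-cavity occupancy and joint-occupancy statistics
#'
#' Splits the gate into two sub-cavities (two disjoint, ordered s
#' intervals) and reports per-frame water counts in each, the frequency of
#' joint occupancy patterns such as (1,1) or (2,0), and which sub-cavity
#' is preferentially occupied (the occupancy-time ratio cavity1:cavity2).
#'
#' @param tracks list of \linkS4class{WaterTrack} objects from
#'   \code{\link{trackWaters}} (tracked in s).
#' @param boundaries list of two numeric length-2 s intervals, disjoint
#'   and ordered along s.
#' @return list with \code{time}, \code{counts} (frames x 2 matrix),
#'   \code{patternFreq} (data.frame of joint patterns and their frame
#'   fractions), \code{preferenceRatio} (total occupancy of sub-cavity 1
#'   over sub-cavity 2) and \code{dominant} (1 or 2).
#' @export
subcavityOccupancy <- function(tracks, boundaries) {
  stopifnot(is.list(boundaries), length(boundaries) == 2L)
  b1 <- sort(boundaries[[1]]); b2 <- sort(boundaries[[2]])
  if (b1[2] > b2[1])
    stop("sub-cavity intervals must be disjoint and ordered along s")
  if (!length(tracks))
    stop("no tracks supplied")
  tm <- sort(unique(unlist(lapply(tracks, function(t) t@time))))
  c1 <- numeric(length(tm)); c2 <- numeric(length(tm))
  for (tr in tracks) {
    i <- match(tr@time, tm)
    in1 <- tr@s >= b1[1] & tr@s <= b1[2]
    in2 <- tr@s >= b2[1] & tr@s <= b2[2]
    c1[i[in1]] <- c1[i[in1]] + 1
    c2[i[in2]] <- c2[i[in2]] + 1
  }
  pat <- paste0("(", c1, ",", c2, ")")
  tab <- sort(table(pat), decreasing = TRUE)
  patternFreq <- data.frame(pattern = names(tab),
                            fraction = as.numeric(tab) / length(tm))
  tot1 <- sum(c1); tot2 <- sum(c2)
  list(time = tm, counts = cbind(cavity1 = c1, cavity2 = c2),
       patternFreq = patternFreq,
       preferenceRatio = if (tot2 > 0) tot1 / tot2 else Inf,
       dominant = if (tot1 >= tot2) 1L else 2L)
}

#' Identify trapped waters
#'
#' A track is called trapped when it resides in the region for at least
#' \code{minResidence} ns without an exit event in that span.
#'
#' @param tracks list of \linkS4class{WaterTrack} objects.
#' @param minResidence minimum continuous residence in ns (default 10).
#' @return integer vector of trapped molecule ids.
#' @export
trappedWaters <- function(tracks, minResidence = 10) {
  ids <- integer(0)
  for (tr in tracks) {
    if (!length(tr@time)) next
    exits <- tr@events$time[tr@events$type == "exit"]
    tStart <- tr@time[1]
    tEnd <- if (length(exits)) max(exits) else tail(tr@time, 1)
    span <- tail(tr@time, 1) - tr@time[1]
    if (!length(exits) && span >= minResidence) ids <- c(ids, tr@molId)
  }
  ids
}
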