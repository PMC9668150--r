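#' Clone phylogeny for a multi-type branching process
#'
#' Defines the clonal structure and rates of a tumor: the initiated
#' (parental) clone 0 plus `k` driver subclones, each founded by a single
#' cell of its parent clone at a scheduled origin time. All clones share the
#' passenger mutation rate `mutation_rate`; each clone has its own birth and
#' death rate, with net growth rate `r = birth - death`.
#'
#' @param birth,death Numeric vectors of length `k + 1`: per-clone birth and
#'   death rates (events per day for simulator use; per year for
#'   patient-facing use), clone 0 first.
#' @param parent Integer vector of length `k`: `parent[i]` is the clone
#'   (in `0..k`) in which driver `i` arose. Must describe a forest rooted at
#'   clone 0.
#' @param t_origin Numeric vector of length `k`: time at which driver `i`
#'   arises. Must exceed the origin time of the parent clone (clone 0
#'   originates at time 0).
#' @param mutation_rate Passenger mutation rate `u` (mutations per unit
#'   time), shared by all clones.
#' @return An object of class `clone_phylogeny` with elements `k`, `birth`,
#'   `death`, `net_rate`, `parent`, `t_origin`, `mutation_rate`.
#' @examples
#' # initiated clone plus one driver subclone with a 100% growth advantage
#' clone_phylogeny(birth = c(0.14, 0.21), death = c(0.07, 0.07),
#'                 parent = 0, t_origin = 60, mutation_rate = 1)
#' @export
clone_phylogeny <- function(birth, death, parent = integer(0),
                            t_origin = numeric(0), mutation_rate = 0) {
  k <- length(parent)
  if (length(birth) != k + 1L || length(death) != k + 1L)
    stop("'birth' and 'death' must have length k + 1 = ", k + 1L)
  if (length(t_origin) != k)
    stop("'t_origin' must have length k = ", k)
  if (any(!is.finite(birth)) || any(!is.finite(death)) ||
      any(birth < 0) || any(death < 0))
    stop("birth and death rates must be finite and non-negative")
  if (!is.finite(mutation_rate) || mutation_rate < 0)
    stop("'mutation_rate' must be finite and non-negative")
  parent <- as.integer(parent)
  if (k > 0) {
    if (any(parent < 0L | parent > k))
      stop("'parent' entries must lie in 0..k")
    # acyclicity: following parents from any clone must reach clone 0
    for (i in seq_len(k)) {
      seen <- integer(0)
      node <- i
      while (node != 0L) {
        if (node %in% seen) stop("'parent' map contains a cycle")
        seen <- c(seen, node)
        node <- parent[node]
      }
    }
    origin_all <- c(0, t_origin)
    if (any(!is.finite(t_origin)) || any(t_origin <= origin_all[parent + 1L]))
      stop("each driver's origin time must exceed its parent clone's")
  }
  structure(
    list(k = k, birth = birth, death = death, net_rate = birth - death,
         parent = parent, t_origin = as.numeric(t_origin),
         mutation_rate = mutation_rate),
    class = "clone_phylogeny")
}

#' @export
print.clone_phylogeny <- function(x, ...) {
  cat("Clone phylogeny:", x$k, "driver subclone(s), u =", x$mutation_rate, "\n")
  df <- data.frame(clone = 0:x$k, parent = c(NA, x$parent),
                   birth = x$birth, death = x$death, net_rate = x$net_rate,
                   t_origin = c(0, x$t_origin))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Observation schedule for a simulated tumor
#'
#' The tumor is bulk "sequenced" (its full state recorded) at
#' `first_obs_time` and again `delta` time units later, mirroring two
#' longitudinal sequencing measurements.
#'
#' @param first_obs_time Time of the first observation; must exceed all
#'   driver origin times of the phylogeny it is used with.
#' @param delta Time between the two observations (> 0).
#' @return An object of class `sim_schedule`.
#' @export
sim_schedule <- function(first_obs_time, delta) {
  if (!is.finite(first_obs_time) || first_obs_time <= 0)
    stop("'first_obs_time' must be a positive finite time")
  if (!is.finite(delta) || delta <= 0)
    stop("'delta' must be a positive finite time")
  structure(list(first_obs_time = first_obs_time, delta = delta),
            class = "sim_schedule")
}

#' Standard simulated tumor regimes
#'
#' Pre-defined parameter sets for the three modes of tumor growth used in
#' the validation studies (rates in events/day), with a choice of clonal
#' layout. The fast-growing regime has `b = 0.14`, `d = 0.07`
#' (`r = 0.07`/day); the slow-growing regime keeps the death rate and
#' reduces the birth rate to give `r = 0.025`/day; the no-death regime has
#' `b = r = 0.07`, `d = 0`. Driver subclones double their parent's net rate
#' (a selective growth advantage of 100%) by raising the birth rate; in the
#' sibling layout the second driver confers a 150% advantage so the two
#' subclones are distinguishable. Schedules are chosen so tumors reach
#' roughly `1e5` cells at the second observation.
#'
#' @param regime One of `"fast"`, `"slow"`, `"nodeath"`.
#' @param layout Clonal structure: `"single"` (one driver subclone),
#'   `"none"` (clone 0 only), `"nested"` (driver 2 arises inside clone 1) or
#'   `"sibling"` (both drivers arise in clone 0).
#' @param u Passenger mutation rate (mutations/day).
#' @return A list with elements `phylo` (a [clone_phylogeny()]) and
#'   `schedule` (a [sim_schedule()]).
#' @export
tumor_regime <- function(regime = c("fast", "slow", "nodeath"),
                         layout = c("single", "none", "nested", "sibling"),
                         u = 1) {
  regime <- match.arg(regime)
  layout <- match.arg(layout)
  # schedules keep every clone macroscopic (exclusive fraction above the
  # default f2 = 0.2) at the second observation, where the subclonal count
  # is measured, and tumors near 1e5 cells
  base <- switch(regime,
    fast    = list(b = 0.14,  d = 0.07, t1 = 80,  t = 65,  delta = 20),
    slow    = list(b = 0.095, d = 0.07, t1 = 160, t = 150, delta = 40),
    nodeath = list(b = 0.07,  d = 0,    t1 = 80,  t = 65,  delta = 20))
  r <- base$b - base$d
  # driver raises the birth rate: r_child = (1 + g) * r_parent
  drv <- function(b_par, d_par, g) c(b_par + g * (b_par - d_par), d_par)
  if (layout == "none") {
    phylo <- clone_phylogeny(base$b, base$d, mutation_rate = u)
    sched <- sim_schedule(base$t1 + base$t, base$delta)
  } else if (layout == "single") {
    c1 <- drv(base$b, base$d, 1)
    phylo <- clone_phylogeny(c(base$b, c1[1]), c(base$d, c1[2]),
                             parent = 0, t_origin = base$t1,
                             mutation_rate = u)
    sched <- sim_schedule(base$t1 + base$t, base$delta)
  } else if (layout == "nested") {
    c1 <- drv(base$b, base$d, 1)
    c2 <- drv(c1[1], c1[2], 1)
    tt <- switch(regime,
      fast    = list(t1 = 63, t2 = 96, t = 19, delta = 15),
      slow    = list(t1 = 176, t2 = 268, t = 54, delta = 42),
      nodeath = list(t1 = 63, t2 = 96, t = 19, delta = 15))
    phylo <- clone_phylogeny(c(base$b, c1[1], c2[1]),
                             c(base$d, c1[2], c2[2]),
                             parent = c(0, 1),
                             t_origin = c(tt$t1, tt$t2), mutation_rate = u)
    sched <- sim_schedule(tt$t2 + tt$t, tt$delta)
  } else {
    c1 <- drv(base$b, base$d, 1)
    c2 <- drv(base$b, base$d, 1.5)
    tt <- switch(regime,
      fast    = list(t1 = 63, t2 = 76, t = 39, delta = 15),
      slow    = list(t1 = 176, t2 = 213, t = 109, delta = 42),
      nodeath = list(t1 = 63, t2 = 76, t = 39, delta = 15))
    phylo <- clone_phylogeny(c(base$b, c1[1], c2[1]),
                             c(base$d, c1[2], c2[2]),
                             parent = c(0, 0),
                             t_origin = c(tt$t1, tt$t2), mutation_rate = u)
    sched <- sim_schedule(tt$t2 + tt$t, tt$delta)
  }
  list(phylo = phylo, schedule = sched)
}

# cumulative clade membership: for each clone, itself plus all descendants
clone_descendants <- function(parent, k = length(parent)) {
  lapply(0:k, function(i) {
    members <- i
    repeat {
      add <- which(parent %in% members)
      add <- setdiff(add, members)
      if (!length(add)) break
      members <- c(members, add)
    }
    sort(members)
  })
}
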