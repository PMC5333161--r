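# shared builders and independent oracles for the test suite

# single-replicate profile from a plain value vector
mk_profile <- function(id, values, kind = "metabolite", condition = "0mM",
                       times = seq_along(values) - 1, units = "uM",
                       n_rep = 1L) {
  ts_profile(id, kind, condition, times,
             lapply(values, function(v) rep(v, n_rep)), units)
}

mk_dataset <- function(...) profile_dataset(list(...))

# definitional Pearson r, written as an explicit accumulation loop so it
# shares no code path with pearson_r()/cor()
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    dx <- x[i] - mx
    dy <- y[i] - my
    num <- num + dx * dy
    sx <- sx + dx * dx
    sy <- sy + dy * dy
  }
  if (sx == 0 || sy == 0) return(NA_real_)
  num / sqrt(sx * sy)
}

# hand-written piecewise reading of the five-bin display legend
oracle_bin <- function(r) {
  if (is.na(r)) return("na")
  if (r > 0.9) return("strong_pos")
  if (r > 0.5) return("pos")
  if (r >= 0) return("weak_pos")
  if (r >= -0.5) return("neg")
  "strong_neg"
}

# a tiny 3-node / 2-edge pathway map used across map tests
toy_map <- function() {
  nodes <- data.frame(id = c("GLC", "PYR", "LAC"),
                      label = c("Glucose", "Pyruvate", "Lactate"),
                      x = c(10, 60, 110), y = c(20, 20, 20),
                      stringsAsFactors = FALSE)
  nodes$compound_ids <- I(list("C00031", "C00022", "C00186"))
  edges <- data.frame(id = c("e1", "e2"), source = c("GLC", "PYR"),
                      target = c("PYR", "LAC"), reversible = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  edges$genes <- I(list(c("Gapdh", "Pgk"), "Ldha"))
  pathway_map(nodes, edges, name = "toy glycolysis")
}

# random multi-entity dataset on a shared grid (for oracle comparisons)
random_dataset <- function(n_entities, n_times = 6L, condition = "0mM") {
  profs <- lapply(seq_len(n_entities), function(i)
    mk_profile(sprintf("E%02d", i), stats::runif(n_times, 1, 100),
               condition = condition))
  profile_dataset(profs)
}

# every subtree of a dendrogram must occupy contiguous leaf positions
subtree_contiguous <- function(hc) {
  leafsets <- vector("list", nrow(hc$merge))
  pos <- match(seq_along(hc$labels), hc$order)
  ok <- TRUE
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(id)
      if (id < 0) -id else leafsets[[id]]))
    leafsets[[i]] <- members
    p <- sort(pos[members])
    if (!all(diff(p) == 1)) ok <- FALSE
  }
  ok
}
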