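# independent brute-force oracle for elementary cycles: try every node
# subset and every cyclic order of it, keeping orders whose consecutive
# edges (and the closing edge) all exist; usable for small graphs only
brute_force_cycles <- function(nodes, edges) {
  has_edge <- function(u, w) any(edges$from == u & edges$to == w)
  canon <- function(l) {
    i <- which(l == min(l))[1L]
    paste(c(l[seq(i, length(l))], l[seq_len(i - 1L)]), collapse = "\r")
  }
  found <- character(0)
  for (u in nodes) if (has_edge(u, u)) found <- c(found, canon(u))
  for (k in 2:length(nodes)) {
    if (k > length(nodes)) break
    for (subset in utils::combn(nodes, k, simplify = FALSE)) {
      first <- subset[1L]
      perms <- perm_all(subset[-1L])
      for (p in perms) {
        cyc <- c(first, p)
        ok <- all(vapply(seq_along(cyc), function(i) {
          has_edge(cyc[i], cyc[if (i == length(cyc)) 1L else i + 1L])
        }, logical(1)))
        if (ok) found <- c(found, canon(cyc))
      }
    }
  }
  sort(unique(found))
}

perm_all <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(perm_all(x[-i]), function(p) c(x[i], p)))
  out
}

canon_cycles <- function(loops) {
  canon <- function(l) {
    i <- which(l == min(l))[1L]
    paste(c(l[seq(i, length(l))], l[seq_len(i - 1L)]), collapse = "\r")
  }
  sort(vapply(loops, canon, character(1)))
}

# a raw dependency_graph from an edge list, bypassing model validation (so
# cyclic instantaneous graphs can be fed to the ordering/enumeration ops)
raw_graph <- function(nodes, from = character(0), to = character(0),
                      integ_from = character(0), integ_to = character(0)) {
  structure(list(
    nodes = nodes,
    instantaneous_edges = data.frame(from = from, to = to,
                                     stringsAsFactors = FALSE),
    integration_edges = data.frame(from = integ_from, to = integ_to,
                                   stringsAsFactors = FALSE)),
    class = "dependency_graph")
}

# single stock with one constant rate; rate_value = 0 gives pure conservation
single_stock_model <- function(rate_value = 0, initial = 1) {
  sd_model(list(
    sd_variable("inflow", "rate", equation = substitute(r + 0 * level,
                                                        list(r = rate_value)),
                dependencies = "level"),
    sd_variable("level", "stock", initial_value = initial, rates = "inflow")),
    name = "single_stock")
}

# dy/dt = -y from y(0)=1: closed form exp(-t)
decay_model <- function(initial = 1) {
  sd_model(list(
    sd_variable("outflow", "rate", equation = quote(-level)),
    sd_variable("level", "stock", initial_value = initial, rates = "outflow")),
    name = "decay")
}

# the four feedback loops read off the causal-loop diagram (delay-collapsed
# naming); the closing edge returns to the first member
wfc_printed_loops <- function() {
  list(
    c("family_involvement", "fiwc", "job_satisfaction_increment",
      "job_satisfaction", "job_performance", "job_pressure", "wifc",
      "family_satisfaction_increment", "family_satisfaction"),
    c("family_pressure", "fiwc", "job_satisfaction_increment",
      "job_satisfaction", "job_performance", "job_pressure", "wifc",
      "family_satisfaction_increment", "family_satisfaction",
      "family_performance"),
    c("job_pressure", "wifc", "family_satisfaction_increment",
      "family_satisfaction", "family_performance", "family_pressure",
      "fiwc", "job_satisfaction_increment", "job_satisfaction",
      "job_performance"),
    c("job_involvement", "wifc", "family_satisfaction_increment",
      "family_satisfaction", "family_performance", "family_pressure",
      "fiwc", "job_satisfaction_increment", "job_satisfaction"))
}
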