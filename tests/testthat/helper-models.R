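# Shared model fixtures, built once per test run. All heavier objects
# (equilibrated standard models) are cached so independent test files can
# reuse them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

std_model <- function() cached("std", standard_model())
std_eq <- function() cached("std_eq", equilibrate(std_model()))

passive_model <- function() {
  cached("passive", standard_model(include = character(0)))
}
passive_eq <- function() cached("passive_eq", equilibrate(passive_model()))

hcn_model <- function() cached("hcn", standard_model(include = "hcn"))
hcn_eq <- function() cached("hcn_eq", equilibrate(hcn_model()))

nak_model <- function() {
  cached("nak", standard_model(include = c("na", "kdr")))
}
nak_eq <- function() cached("nak_eq", equilibrate(nak_model()))

# site indices nearest the requested path distances (um)
sites_near <- function(model, dists) {
  s <- model$synapse_sites
  idx <- integer(0)
  for (d in dists) {
    free <- setdiff(seq_len(nrow(s)), idx)
    idx <- c(idx, free[which.min(abs(s$path_distance[free] - d))])
  }
  sort(idx)
}

single_epsp_peak <- function(model, eq, dist_um, duration = 700) {
  r <- advance(model, eq$state, duration,
               stimuli = data.frame(site = sites_near(model, dist_um),
                                    onset = 100, duration = 3))
  max(r$traces[[1]]$values) - eq$vrest
}
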