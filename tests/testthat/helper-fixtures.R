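# Shared fixtures, built once per test run. The synthetic construct mirrors
# the assayed architecture: ~5.5 kb vector with a unique blunt-cutting
# linearization site, 2 kb repeat unit, yeast-like background molecules.
fixture_env <- new.env()

fx_map <- function() {
  if (is.null(fixture_env$map)) fixture_env$map <- example_plasmid_map()
  fixture_env$map
}

fx_pool <- function() {
  if (is.null(fixture_env$pool)) fixture_env$pool <- example_background_pool()
  fixture_env$pool
}

fx_template <- function(k) build_template(fx_map(), k)

# random ACGT string drawn from the current RNG stream
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# target-only mixture over the given copy numbers
target_mix <- function(props) mixture_spec(props, 0, NULL)

seqs_of <- function(batch) setNames(batch$reads$seq, batch$reads$read_id)

# independent per-read truth lookup
truth_copy <- function(batch, ids) {
  batch$truth$copy_number[match(ids, batch$truth$read_id)]
}
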