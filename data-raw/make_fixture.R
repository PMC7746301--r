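# Generating run for the pinned reference fixture in R/scenario.R.
# Not executed at build or load time; re-running it reproduces the
# literals (up to printing precision) from the seeds alone.
library(loopstate)

res <- search_bistable(parameter_ranges(), n_samples = 30, seed = 1000)
# hits: instance seeds 1001, 1007, 1010, 1015; 1015 chosen because its
# bistable window sits well inside the default sweep range.
params <- sample_parameterization(parameter_ranges(), seed = 1015)

d <- sweep_mu(params, exp(seq(log(1e-2), log(1e2), length.out = 80)),
              seed = 1)
print(d)
# stable-count pattern 1 -> 2 -> 1; folds bisected near 7.274 and 28.16;
# outermost grid-certified bistable mu values: 7.693 and 27.74 (pinned as
# the fixture window).
dput(lapply(params$responses, unclass))
dput(params$tau)
dput(params$u)
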