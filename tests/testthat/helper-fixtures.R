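# Small in-code fixtures shared across test files.

# A tiny labelled dataset with gaussian images.
makeTinyDataset <- function(n = 10L, shape = c(8L, 8L),
                            task = "classification", seed = 1L,
                            k = 1L) {
  set.seed(seed)
  imgs <- replicate(n, array(rnorm(prod(shape)), shape), simplify = FALSE)
  y <- if (task == "classification") rep_len(c(0, 1), n)
       else runif(n, 0, 10)
  cf <- matrix(rnorm(n * k), ncol = k)
  ConfoundedDataset(imgs, y, cf, task = task)
}

# A small architecture for fast training tests: 8x8 input, two stacks.
tinyArch <- function(k = 1L) {
  cfnetArchitecture(c(8L, 8L), nStacks = 2L, nFiltersStart = 4L,
                    headHiddenWidth = 8L, kOutputs = k)
}

# Regression dataset with a binary matching variable and tiny images, for
# the bootstrap-matching tests. Outcomes of level 1 are shifted upward.
makeMatchingDataset <- function(n = 300L, shift = 1, seed = 1L) {
  set.seed(seed)
  imgs <- replicate(n, array(rnorm(4), c(2L, 2L)), simplify = FALSE)
  sex <- rep_len(c(0, 1), n)
  y <- runif(n, 75, 175) + shift * sex
  ConfoundedDataset(imgs, y, rnorm(n), task = "regression",
                    extra = data.frame(sex = sex))
}
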