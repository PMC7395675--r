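# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Moderate synthetic cohort shared by several suites (~350 exams).
small_cohort <- function() {
  fixture("small_cohort", function() {
    normalize_laterality(simulate_cohort(generator_config(n_patients = 120,
                                                          seed = 42)))
  })
}

small_normative <- function() {
  fixture("small_normative", function() {
    co <- small_cohort()
    suppressWarnings(derive_normative_tables(co[!co$exams$is_glaucoma],
                                             co[co$exams$is_glaucoma]))
  })
}

# Hand-built minimal paired cohort for curation tests.
make_cohort <- function(exams, rnfl = NULL, vf = NULL) {
  n <- nrow(exams)
  structure(
    list(exams = exams,
         rnfl = rnfl %||% matrix(100, n, 768),
         vf = vf %||% matrix(30, n, 52),
         vf_true = NULL,
         config = generator_config()),
    class = "paired_cohort"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle for the network forward pass: plain loops,
# no im2col, following the documented weight layout (kernel row index
# (j - 1) * c_in + c for tap j, input channel c).
brute_force_cnn <- function(model, x_row) {
  arch <- model$arch
  w <- model$weights
  k <- arch$kernel_size
  a <- matrix(x_row / arch$input_scale, ncol = 1)
  nconv <- length(arch$conv_channels)
  for (i in seq_len(nconv)) {
    c_in <- ncol(a)
    c_out <- arch$conv_channels[i]
    l_out <- nrow(a) - k + 1
    z <- matrix(0, l_out, c_out)
    for (p in seq_len(l_out)) {
      for (co in seq_len(c_out)) {
        acc <- w[[paste0("b", i)]][co]
        for (j in seq_len(k)) {
          for (ci in seq_len(c_in)) {
            acc <- acc + a[p + j - 1, ci] * w[[paste0("W", i)]][(j - 1) * c_in + ci, co]
          }
        }
        z[p, co] <- acc
      }
    }
    a <- pmax(z, 0)
  }
  v <- as.vector(a)  # column-major: position fastest, matching flatten order
  nfc <- length(arch$fc_sizes)
  for (j in seq_len(nfc)) {
    z <- drop(v %*% w[[paste0("W", nconv + j)]]) + w[[paste0("b", nconv + j)]]
    v <- if (j < nfc) pmax(z, 0) else z
  }
  v
}
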