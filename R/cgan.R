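#' Discriminator and generator losses of the adversarial game
#'
#' The discriminator minimizes the negated empirical value function of the
#' minimax game, a binary cross-entropy:
#' `d_loss = -[mean(log d_real) + mean(log(1 - d_fake))]`.
#' At the equilibrium where the generator matches the data distribution and
#' the discriminator outputs 1/2 everywhere, `d_loss = log 4`. The generator
#' uses the non-saturating form `g_loss = -mean(log d_fake)`, which has the
#' same fixed point as the original `log(1 - D(G(z)))` objective but does
#' not vanish early in training.
#'
#' @param d_real discriminator outputs on real records, strictly in (0, 1).
#' @param d_fake discriminator outputs on generated records, strictly in
#'   (0, 1).
#' @return scalar loss.
#' @export
d_loss <- function(d_real, d_fake) {
  check_unit_open(d_real)
  check_unit_open(d_fake)
  -(mean(log(d_real)) + mean(log(1 - d_fake)))
}

#' @rdname d_loss
#' @export
g_loss <- function(d_fake) {
  check_unit_open(d_fake)
  -mean(log(d_fake))
}

check_unit_open <- function(p) {
  if (length(p) == 0 || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("discriminator probabilities must lie in [0, 1]")
  }
  invisible(p)
}

#' GAN training configuration
#'
#' Both networks are two-hidden-layer perceptrons (128 and 64 units,
#' leaky-rectifier activations). Defaults: 32-dimensional standard-normal
#' noise, batch size 32, Adam with learning rate 2e-4, 300 epochs,
#' alternating one discriminator step and one generator step per batch.
#'
#' @param noise_dim dimension of the noise prior.
#' @param hidden hidden-layer sizes shared by both networks.
#' @param lr generator Adam learning rate.
#' @param lr_d discriminator Adam learning rate; the two-time-scale
#'   default keeps the discriminator ahead of the generator, which
#'   stabilizes the numeric columns on small tables.
#' @param d_steps discriminator updates per generator update.
#' @param smooth one-sided label-smoothing target for real records
#'   (1 disables smoothing).
#' @param fm_weight weight of the feature-matching auxiliary on the
#'   generator: per batch, the squared distance between generated and real
#'   column means (plus second moments of the numeric columns) is added to
#'   the adversarial objective. This anchors the marginal structure, which
#'   the plain adversarial signal controls only weakly on tables of a few
#'   hundred rows; 0 disables it.
#' @param batch minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed controlling initialization and all sampling.
#' @return a `gan_config` list.
#' @export
gan_config <- function(noise_dim = 32L, hidden = c(128L, 64L), lr = 2e-4,
                       lr_d = lr, d_steps = 1L, smooth = 1,
                       fm_weight = 3, batch = 32L, epochs = 300L,
                       seed = 42L) {
  structure(list(noise_dim = as.integer(noise_dim),
                 hidden = as.integer(hidden), lr = lr, lr_d = lr_d,
                 d_steps = as.integer(d_steps), smooth = smooth,
                 fm_weight = fm_weight,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Train a conditional GAN on a patient cohort
#'
#' Splits the cohort 70/30, fits the encoding map on the training rows,
#' and runs the adversarial game conditioned on the outcome class: both
#' networks receive the one-hot outcome label as extra input, so records
#' can later be generated per class. Generator outputs pass through a
#' per-block softmax on categorical blocks (decoded by arg-max) and are
#' linear on the standardized numeric columns.
#'
#' The training log records, per epoch, the discriminator and generator
#' losses, the discriminator's accuracy at separating held-out real records
#' from fresh generated ones, and a mode-collapse monitor (number of
#' distinct tumor-site categories among 64 probe samples; a warning is
#' issued if the final epoch produces fewer than 6).
#'
#' @param cohort a `patient_cohort` with both outcome classes present.
#' @param config a [gan_config()].
#' @param ratio train fraction for the internal split (default 0.7).
#' @return a `cgan` bundle: generator and discriminator networks, the
#'   encoding map, block layout, config and the training log.
#' @export
gan_fit <- function(cohort, config = gan_config(), ratio = 0.7) {
  if (length(unique(cohort$outcome)) < 2) {
    stop("GAN training needs at least one record per outcome class")
  }
  idx <- split_indices(nrow(cohort), ratio, config$seed)
  train <- cohort[idx$train, , drop = FALSE]
  heldout <- cohort[idx$test, , drop = FALSE]
  enc <- encode_cohort(train)
  x_held <- encode_cohort(heldout, enc$map)$x
  gan_train(enc$x, train$outcome, config, enc$map,
            x_heldout = x_held, labels_heldout = heldout$outcome)
}

#' Core adversarial training loop on an encoded matrix
#'
#' Lower-level entry point used by [gan_fit()]: takes an already encoded
#' training matrix plus its outcome labels. Errors if the labels contain a
#' single class or if a loss becomes non-finite (reporting the epoch).
#'
#' @param x encoded training matrix (rows = records).
#' @param labels factor of outcome classes (`one`/`more`), one per row.
#' @param config a [gan_config()].
#' @param map the `encoding_map` describing `x`'s columns.
#' @param x_heldout,labels_heldout optional held-out encoded records for
#'   the discriminator-accuracy log entry.
#' @return a `cgan` bundle.
#' @export
gan_train <- function(x, labels, config = gan_config(), map,
                      x_heldout = NULL, labels_heldout = NULL) {
  labels <- factor(as.character(labels), levels = outcome_levels())
  if (length(unique(labels)) < 2) {
    stop("GAN training needs at least one record per outcome class")
  }
  stopifnot(nrow(x) == length(labels))
  width <- encoding_width(map)
  stopifnot(ncol(x) == width)
  blocks <- encoding_blocks(map)
  L <- label_onehot(labels)

  with_seed(config$seed, {
    G <- mlp_init(c(config$noise_dim + 2L, config$hidden, width))
    D <- mlp_init(c(width + 2L, config$hidden, 1L))
    sG <- adam_init(G)
    sD <- adam_init(D)
    tG <- 0L
    tD <- 0L
    n <- nrow(x)
    log_rows <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch)
      dl <- gl <- numeric(0)
      for (s in starts) {
        rows <- perm[s:min(s + config$batch - 1, n)]
        b <- length(rows)
        xb <- x[rows, , drop = FALSE]
        lb <- L[rows, , drop = FALSE]

        # --- discriminator step(s) ---
        for (dstep in seq_len(config$d_steps)) {
          z <- matrix(rnorm(b * config$noise_dim), b)
          fake <- g_output(G, z, lb, blocks)$probs
          fr <- mlp_forward(D, cbind(xb, lb))
          ff <- mlp_forward(D, cbind(fake, lb))
          pr <- sigmoid(drop(fr$out))
          pf <- sigmoid(drop(ff$out))
          dl_val <- -(mean(log(pmax(pr, 1e-12))) +
                      mean(log(pmax(1 - pf, 1e-12))))
          # one-sided label smoothing: real target is config$smooth, not 1
          gr <- mlp_backward(D, fr, matrix((pr - config$smooth) / b,
                                           ncol = 1))
          gf <- mlp_backward(D, ff, matrix(pf / b, ncol = 1))
          tD <- tD + 1L
          up <- adam_step(D, add_grads(gr$grads, gf$grads), sD,
                          config$lr_d, tD)
          D <- up$net
          sD <- up$state
        }

        # --- generator step (non-saturating loss) ---
        z <- matrix(rnorm(b * config$noise_dim), b)
        go <- g_output(G, z, lb, blocks)
        fd <- mlp_forward(D, cbind(go$probs, lb))
        pf <- sigmoid(drop(fd$out))
        gl_val <- -mean(log(pmax(pf, 1e-12)))
        bd <- mlp_backward(D, fd, matrix((pf - 1) / b, ncol = 1))
        dProbs <- bd$dX[, seq_len(width), drop = FALSE]
        if (config$fm_weight > 0) {
          # feature matching: pull generated batch moments toward the
          # real batch's column means (and second moments for numerics)
          dm <- colMeans(go$probs) - colMeans(xb)
          dProbs <- dProbs + config$fm_weight *
            matrix(2 * dm / b, b, width, byrow = TRUE)
          num_cols <- numeric_columns(blocks)
          if (length(num_cols)) {
            ds2 <- colMeans(go$probs[, num_cols, drop = FALSE]^2) -
                   colMeans(xb[, num_cols, drop = FALSE]^2)
            dProbs[, num_cols] <- dProbs[, num_cols] +
              config$fm_weight * 4 *
              go$probs[, num_cols, drop = FALSE] *
              matrix(ds2 / b, b, length(num_cols), byrow = TRUE)
          }
        }
        dZout <- transform_backward(dProbs, go$probs, blocks)
        bg <- mlp_backward(G, go$cache, dZout)
        tG <- tG + 1L
        up <- adam_step(G, bg$grads, sG, config$lr, tG)
        G <- up$net
        sG <- up$state

        if (!is.finite(dl_val) || !is.finite(gl_val)) {
          stop(sprintf("GAN training diverged at epoch %d", epoch))
        }
        dl <- c(dl, dl_val)
        gl <- c(gl, gl_val)
      }

      acc <- NA_real_
      if (!is.null(x_heldout) && nrow(x_heldout) > 0) {
        Lh <- label_onehot(factor(as.character(labels_heldout),
                                  levels = outcome_levels()))
        zh <- matrix(rnorm(nrow(x_heldout) * config$noise_dim),
                     nrow(x_heldout))
        fh <- g_output(G, zh, Lh, blocks)$probs
        p_real <- sigmoid(drop(mlp_forward(D, cbind(x_heldout, Lh))$out))
        p_fake <- sigmoid(drop(mlp_forward(D, cbind(fh, Lh))$out))
        acc <- (mean(p_real > 0.5) + mean(p_fake <= 0.5)) / 2
      }
      n_sites <- probe_site_count(G, map, blocks, config)
      log_rows[[epoch]] <- data.frame(epoch = epoch, d_loss = mean(dl),
                                      g_loss = mean(gl),
                                      d_heldout_acc = acc,
                                      n_sites = n_sites)
    }
    log <- do.call(rbind, log_rows)
    if (log$n_sites[nrow(log)] < 6) {
      warning(sprintf(
        "possible mode collapse: only %d distinct tumor-site categories in the final probe",
        log$n_sites[nrow(log)]))
    }
    structure(list(G = G, D = D, config = config, map = map,
                   blocks = blocks, log = log, trained = TRUE),
              class = "cgan")
  })
}

label_onehot <- function(labels) {
  L <- matrix(0, length(labels), 2,
              dimnames = list(NULL, outcome_levels()))
  L[cbind(seq_along(labels), as.integer(labels))] <- 1
  L
}

# generator forward pass + per-block output transform
g_output <- function(G, z, L, blocks) {
  cache <- mlp_forward(G, cbind(z, L))
  raw <- cache$out
  probs <- raw
  for (i in seq_len(nrow(blocks))) {
    if (blocks$type[i] == "categorical") {
      cols <- blocks$start[i]:blocks$end[i]
      probs[, cols] <- softmax_rows(raw[, cols, drop = FALSE])
    }
  }
  list(probs = probs, cache = cache)
}

# gradient of the transform: softmax Jacobian per categorical block
transform_backward <- function(dProbs, probs, blocks) {
  dZ <- dProbs
  for (i in seq_len(nrow(blocks))) {
    if (blocks$type[i] == "categorical") {
      cols <- blocks$start[i]:blocks$end[i]
      p <- probs[, cols, drop = FALSE]
      dp <- dProbs[, cols, drop = FALSE]
      dZ[, cols] <- p * (dp - rowSums(dp * p))
    }
  }
  dZ
}

numeric_columns <- function(blocks) {
  idx <- which(blocks$type == "numeric")
  unlist(lapply(idx, function(i) blocks$start[i]:blocks$end[i]))
}

add_grads <- function(a, b) {
  Map(function(ga, gb) list(W = ga$W + gb$W, b = ga$b + gb$b), a, b)
}

probe_site_count <- function(G, map, blocks, config, n_probe = 64L) {
  z <- matrix(rnorm(n_probe * config$noise_dim), n_probe)
  lab <- factor(rep(outcome_levels(), length.out = n_probe),
                levels = outcome_levels())
  probs <- g_output(G, z, label_onehot(lab), blocks)$probs
  dec <- decode_matrix(probs, map)
  length(unique(as.character(dec$site)))
}

#' Draw decoded records from a trained generator
#'
#' Low-level sampler behind [gan_generate()]: feeds standard-normal noise
#' and the given conditioning labels through the generator and decodes the
#' output with the bundle's encoding map — no patient-record invariants
#' are enforced. Works with any encoding map, including toy single-variable
#' domains.
#'
#' @param bundle a trained `cgan`.
#' @param n number of records.
#' @param labels factor of conditioning classes (`one`/`more`), length `n`.
#' @param seed integer seed.
#' @return the decoded data frame.
#' @export
gan_sample_raw <- function(bundle, n, labels, seed = bundle$config$seed + 1L) {
  if (!inherits(bundle, "cgan") || !isTRUE(bundle$trained)) {
    stop("gan_sample_raw needs a trained cgan bundle")
  }
  labels <- factor(as.character(labels), levels = outcome_levels())
  stopifnot(length(labels) == n)
  with_seed(seed, {
    z <- matrix(rnorm(n * bundle$config$noise_dim), n)
    probs <- g_output(bundle$G, z, label_onehot(labels),
                      bundle$blocks)$probs
    decode_matrix(probs, bundle$map)
  })
}

#' Generate a decoded synthetic cohort from a trained GAN
#'
#' Labels are inputs, not sampled: exactly `round(n * label_mix["one"])`
#' records are generated under class "one" and the rest under "more"
#' (default 50/50). After decoding, patient-record invariants are enforced:
#' the tele-visit count is set to 1 for class "one" and at least 2 for
#' class "more"; bone metastases imply metastatic disease; prostate records
#' are male, gynecological and breast records female.
#'
#' @param bundle a trained `cgan` bundle.
#' @param n number of records (>= 0).
#' @param label_mix named probabilities for classes `one` and `more`.
#' @param seed integer seed (defaults to the training seed plus one).
#' @return a `patient_cohort` of `n` rows.
#' @export
gan_generate <- function(bundle, n, label_mix = c(one = 0.5, more = 0.5),
                         seed = bundle$config$seed + 1L) {
  if (!inherits(bundle, "cgan") || !isTRUE(bundle$trained)) {
    stop("gan_generate needs a trained cgan bundle")
  }
  stopifnot(n >= 0)
  if (n == 0) return(empty_cohort())
  label_mix <- label_mix / sum(label_mix)
  n_one <- round(n * label_mix[["one"]])
  labels <- factor(rep(outcome_levels(), c(n_one, n - n_one)),
                   levels = outcome_levels())
  dec <- gan_sample_raw(bundle, n, labels, seed)
  with_seed(seed + 1L, {
    dec$n_televisits <- ifelse(labels == "one", 1L,
                               pmax(dec$n_televisits, 2L))
    dec$metastatic <- pmax(dec$metastatic, dec$bone_mets)
    g <- as.character(dec$gender)
    g[dec$site == "prostate"] <- "male"
    g[dec$site %in% c("gynecological", "breast")] <- "female"
    dec$gender <- factor(g, levels = gender_levels())
    cohort <- data.frame(patient_id = seq_len(n), dec[, c("age", "gender",
      "site", "metastatic", "bone_mets", "btcp", "neuropathic", "ecog",
      "med_gt60", "n_televisits")], outcome = labels,
      check.names = FALSE)
    class(cohort) <- c("patient_cohort", "data.frame")
    cohort
  })
}

#' @exportS3Method
print.cgan <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("Conditional GAN: %d epochs, noise dim %d, hidden [%s]\n",
              x$config$epochs, x$config$noise_dim,
              paste(x$config$hidden, collapse = ", ")))
  cat(sprintf("  final d_loss %.3f, g_loss %.3f, held-out D accuracy %s\n",
              last$d_loss, last$g_loss,
              ifelse(is.na(last$d_heldout_acc), "NA",
                     sprintf("%.2f", last$d_heldout_acc))))
  invisible(x)
}

#' Fit a stand-alone discriminator between two encoded samples
#'
#' Trains the discriminator network alone (no conditioning) to minimize
#' [d_loss()] between a fixed "real" sample and a fixed "fake" sample by
#' Adam gradient descent. Useful for post-hoc real-vs-generated probes;
#' with large samples from known discrete densities its output converges
#' to the optimal discriminator `p_data(x) / (p_data(x) + p_g(x))`.
#'
#' @param x_real,x_fake numeric matrices with identical column counts.
#' @param hidden hidden-layer sizes.
#' @param lr Adam learning rate.
#' @param steps full-batch gradient steps.
#' @param seed integer seed.
#' @return a `discriminator_fit` object; use `predict(fit, x)` for
#'   probabilities that rows of `x` are "real".
#' @export
fit_discriminator <- function(x_real, x_fake, hidden = c(64L, 32L),
                              lr = 5e-3, steps = 2000L, seed = 1L) {
  stopifnot(ncol(x_real) == ncol(x_fake))
  with_seed(seed, {
    D <- mlp_init(c(ncol(x_real), hidden, 1L))
    st <- adam_init(D)
    nr <- nrow(x_real)
    nf <- nrow(x_fake)
    for (t in seq_len(steps)) {
      fr <- mlp_forward(D, x_real)
      ff <- mlp_forward(D, x_fake)
      pr <- sigmoid(drop(fr$out))
      pf <- sigmoid(drop(ff$out))
      gr <- mlp_backward(D, fr, matrix((pr - 1) / nr, ncol = 1))
      gf <- mlp_backward(D, ff, matrix(pf / nf, ncol = 1))
      up <- adam_step(D, add_grads(gr$grads, gf$grads), st, lr, t)
      D <- up$net
      st <- up$state
    }
    structure(list(net = D), class = "discriminator_fit")
  })
}

#' @export
predict.discriminator_fit <- function(object, newdata, ...) {
  sigmoid(drop(mlp_forward(object$net, as.matrix(newdata))$out))
}

#' Persist / restore a trained GAN bundle
#'
#' Writes the bundle as plain-text files in a directory: `config.json`,
#' `map.json` (the encoding map), `weights.json` (both networks) and
#' `log.csv` (the per-epoch training log).
#'
#' @param bundle a trained `cgan`.
#' @param dir directory path (created if missing).
#' @return `gan_load` returns a `cgan`; `gan_save` returns `dir` invisibly.
#' @export
gan_save <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cgan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  write_encoding_map(bundle$map, file.path(dir, "map.json"))
  nets <- list(G = net_to_list(bundle$G), D = net_to_list(bundle$D))
  jsonlite::write_json(nets, file.path(dir, "weights.json"), digits = NA)
  write.csv(bundle$log, file.path(dir, "log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname gan_save
#' @export
gan_load <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- gan_config(noise_dim = cfg$noise_dim, hidden = cfg$hidden,
                       lr = cfg$lr, lr_d = cfg$lr_d,
                       d_steps = cfg$d_steps, smooth = cfg$smooth,
                       fm_weight = cfg$fm_weight, batch = cfg$batch,
                       epochs = cfg$epochs, seed = cfg$seed)
  map <- read_encoding_map(file.path(dir, "map.json"))
  nets <- jsonlite::read_json(file.path(dir, "weights.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  log <- read.csv(file.path(dir, "log.csv"))
  structure(list(G = net_from_list(nets$G), D = net_from_list(nets$D),
                 config = config, map = map,
                 blocks = encoding_blocks(map), log = log, trained = TRUE),
            class = "cgan")
}

net_to_list <- function(net) {
  list(sizes = net$sizes,
       layers = lapply(net$layers, function(l) list(W = l$W, b = l$b)))
}

net_from_list <- function(obj) {
  layers <- lapply(obj$layers, function(l) {
    list(W = as.matrix(l$W), b = as.numeric(l$b))
  })
  structure(list(layers = layers, sizes = as.integer(obj$sizes)),
            class = "telepain_mlp")
}
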