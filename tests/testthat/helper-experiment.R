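# Shared mixed-width phantom experiment used by several acceptance checks:
# 40 phantoms under the default generator conditions (size 300, 5 vessels,
# widths 1.5-2.5, moderate noise), split 20 train / 20 test, the 11-scale
# multiscale filter fused by the 3-8 network. Computed once per session.

.acceptance_cache <- new.env(parent = emptyenv())

acceptance_experiment <- function() {
  if (!is.null(.acceptance_cache$run)) return(.acceptance_cache$run)
  phantoms <- lapply(1:40, function(s) generate_phantom(phantom_config(seed = s)))
  masks <- lapply(phantoms, `[[`, "gt_mask")
  stacks <- lapply(phantoms, function(p)
    multiscale_response(p$image, seq(1.5, 2.5, by = 0.1)))
  rm(phantoms)
  tr <- 1:20; te <- 21:40
  model <- train_network(stacks[tr], masks[tr],
                         network_architecture(11, c(3, 8)),
                         training_config(seed = 1, max_samples = 150000L))
  fused_tr <- lapply(stacks[tr], function(s) predict_image(model, s))
  fused_te <- lapply(stacks[te], function(s) predict_image(model, s))
  single_te <- vapply(1:11, function(k)
    dataset_auc(lapply(stacks[te], function(s) s$responses[[k]]), masks[te]),
    numeric(1))
  per_image <- vapply(seq_along(te), function(i) {
    fused <- auc(roc(fused_te[[i]], masks[te][[i]]))
    best_single <- max(vapply(1:11, function(k)
      auc(roc(stacks[te][[i]]$responses[[k]], masks[te][[i]])), numeric(1)))
    c(fused = fused, best_single = best_single)
  }, numeric(2))
  .acceptance_cache$run <- list(
    stacks = stacks, masks = masks, tr = tr, te = te, model = model,
    fused_tr = fused_tr, fused_te = fused_te,
    az_train = dataset_auc(fused_tr, masks[tr]),
    az_test = dataset_auc(fused_te, masks[te]),
    single_scale_test = single_te, per_image = per_image)
  .acceptance_cache$run
}
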