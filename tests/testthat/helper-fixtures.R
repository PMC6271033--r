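# deterministic small fixtures, built in code

rand_cube <- function(nl = 2, ns = 3, nb = 4, seed = 42,
                      kind = "raw_counts", lo = 100, hi = 5000) {
  set.seed(seed)
  Hypercube(array(runif(nl * ns * nb, lo, hi), c(nl, ns, nb)),
            wavelengths = seq(1000, 2400, length.out = nb),
            signalKind = kind)
}

rand_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# a small labeled scene: 6 disk wells (one per species x organ) on a
# 96 x 120 stage, rendered with the default library
small_scene <- function(seed = 7, noise = defaultSceneNoise(), r = 9,
                        mats = c("ang_root", "ang_leaf", "purp_root",
                                 "purp_leaf", "pall_root", "pall_leaf")) {
  lib <- defaultEchinaceaLibrary()
  pos <- expand.grid(cy = c(26, 68), cx = c(22, 60, 98))
  wells <- lapply(seq_along(mats), function(i) {
    list(cy = pos$cy[i], cx = pos$cx[i], r = r,
         label = paste0(mats[i], "_w"), class_hint = lib[[mats[i]]]$class,
         material = mats[i])
  })
  renderScene(sceneSpec(wells, shape = c(96L, 120L), noise = noise,
                        seed = seed), lib)
}

# truth foreground mask (TRUE = inside any well) for a rendered scene
truth_foreground <- function(scene) {
  scene$truth$classMap != "stage"
}
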