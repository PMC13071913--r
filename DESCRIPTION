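Package: parchscape
Title: Hydropathy Landscapes of Nucleosomes from Annealing Hydration Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Residue-resolved hydropathy analysis of nucleosome and
    dinucleosome structures. Computes PARCH (Protocol for Assigning a
    Residue's Character on a Hydropathy scale) values from hydration-shell
    water-count series recorded along a thermal annealing ramp, with
    separate scores for the DNA sugar-phosphate backbone and the
    nucleobases. Provides the spatial classifiers used at the histone-DNA
    interface (proximal/distal DNA, DNA-contacting histone residues,
    dinucleosome inner/outer, acidic-patch and arginine-anchor selections),
    paired-system delta-PARCH differencing (DNA present minus DNA removed;
    methylated minus unmethylated), in-silico cytosine C5 methylation,
    kernel-density and rank-sum distributional statistics, and synthetic
    toy nucleosome/dinucleosome generators with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
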