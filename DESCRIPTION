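Package: flyrig
Title: Virtual Open-Hardware Imaging and Stimulation Rig for Small-Animal Neurogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free re-implementation of the computational core of a
    low-cost Raspberry Pi + Arduino behavioural rig: a virtual Peltier-thermistor
    feedback loop, an LED-ring and serial-command device model, a microsecond
    stimulus scheduler, and the image-analysis procedures used with such rigs
    (calcium kymographs and peristaltic-wave detection, point-spread-function
    estimation from fluorescent beads, proboscis-extension and fin-bout
    quantification, larval length and contraction metrics, minimal centroid
    tracking). A synthetic-scene camera simulator with per-scene ground truth
    makes every analysis testable without hardware or animals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    igraph,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
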