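# Bundled data

- `synthetic_connectome_edges.tsv` — a **synthetic** connectome-scale
  fixture (277 nodes, 2,105 edges) produced by
  `synthetic_connectome(277, 2105, seed = 926)` and exported with
  `write_edgelist()`. It emulates only the gross statistics of a small
  neuronal connectome (connected, modular, a few hubs) so that loader and
  metric code paths can be exercised without external data. It is **not**
  biological data.

To run the real-data checks, place the *C. elegans* structural
connectome (277 neurons, 2,105 synaptic connections; Achacoso & Yamamoto
/ White et al. reconstructions) in this directory as
`celegans_edges.tsv`, a two-column tab-separated edge list. The loader
symmetrises and binarises whatever it is given.
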