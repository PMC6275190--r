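# Minimal network specification: two five-neuron assemblies, an excitatory
# feed-forward projection, and a plastic return projection.
step_ms: 1
populations:
  - id: a
    size: 5
    model: lif_adapt
    params:
      membrane_decay: 0.2
      threshold: 1
  - id: b
    size: 5
    model: lif_adapt
projections:
  - name: ab
    src: a
    tgt: b
    pre: [1, 2, 3, 4, 5]
    post: [1, 2, 3, 4, 5]
    weight: 0.3
    delay: 1
  - name: ba
    src: b
    tgt: a
    pre: [1, 2, 3, 4, 5]
    post: [1, 2, 3, 4, 5]
    weight: 0.02
    delay: 1
    plasticity: stdp_hebbian
    w_max: 0.12
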