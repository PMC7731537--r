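# Carbon atom maps for the first oxidative turn of the TCA cycle fed by
# glutamine anaplerosis. IUPAC numbering for each acid. Map entries are
# destination_carbon: source_carbon; source 0 denotes a carbon entering from
# an unlabeled co-substrate (acetyl-CoA at citrate synthase). `lost` lists
# source carbons released as CO2. `symmetric_product` marks products whose
# two orientations are chemically indistinguishable (succinate, fumarate):
# both orientations are retained as equiprobable positional states.
version: 1
tracer_substrate: glutamine
metabolites:
  glutamine: 5
  glutamate: 5
  alpha_ketoglutarate: 5
  succinate: 4
  fumarate: 4
  malate: 4
  oxaloacetate: 4
  aspartate: 4
  citrate: 6
reactions:
  - name: glutaminase
    from: glutamine
    to: glutamate
    map: {1: 1, 2: 2, 3: 3, 4: 4, 5: 5}
  - name: glutamate_dehydrogenase
    from: glutamate
    to: alpha_ketoglutarate
    map: {1: 1, 2: 2, 3: 3, 4: 4, 5: 5}
  - name: alpha_ketoglutarate_dehydrogenase
    from: alpha_ketoglutarate
    to: succinate
    map: {1: 2, 2: 3, 3: 4, 4: 5}
    lost: [1]
    symmetric_product: true
  - name: succinate_dehydrogenase
    from: succinate
    to: fumarate
    map: {1: 1, 2: 2, 3: 3, 4: 4}
    symmetric_product: true
  - name: fumarase
    from: fumarate
    to: malate
    map: {1: 1, 2: 2, 3: 3, 4: 4}
  - name: malate_dehydrogenase
    from: malate
    to: oxaloacetate
    map: {1: 1, 2: 2, 3: 3, 4: 4}
  - name: aspartate_aminotransferase
    from: oxaloacetate
    to: aspartate
    map: {1: 1, 2: 2, 3: 3, 4: 4}
  - name: citrate_synthase
    from: oxaloacetate
    to: citrate
    map: {1: 0, 2: 0, 3: 1, 4: 2, 5: 3, 6: 4}
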