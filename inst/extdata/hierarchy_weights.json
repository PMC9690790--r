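{
  "name": "stabilization_effect",
  "note": "Expert-panel (n=20) AHP weights. Criterion and sub-criterion local weights are the published values; leaf nodes carry the published comprehensive weights (independently rounded to 3 decimals, hence summing to 1.003) and their local weights are derived by within-parent renormalization.",
  "children": [
    {
      "name": "soil", "weight": 0.544,
      "children": [
        {
          "name": "soil_fertility", "weight": 0.295,
          "children": [
            {"name": "pH", "comprehensive": 0.052},
            {"name": "SOM", "comprehensive": 0.021},
            {"name": "CEC", "comprehensive": 0.017},
            {"name": "A-N", "comprehensive": 0.021},
            {"name": "A-P", "comprehensive": 0.022},
            {"name": "A-K", "comprehensive": 0.022}
          ]
        },
        {
          "name": "soil_heavy_metal", "weight": 0.705,
          "children": [
            {"name": "AHM", "comprehensive": 0.300},
            {"name": "THM", "comprehensive": 0.091}
          ]
        }
      ]
    },
    {
      "name": "crop", "weight": 0.316,
      "children": [
        {
          "name": "crop_growth", "weight": 0.265,
          "children": [
            {"name": "biomass", "comprehensive": 0.025},
            {"name": "production", "comprehensive": 0.060}
          ]
        },
        {
          "name": "pollution_accumulation", "weight": 0.735,
          "children": [
            {"name": "edible_hm", "comprehensive": 0.150},
            {"name": "aboveground_hm", "comprehensive": 0.028},
            {"name": "root_hm", "comprehensive": 0.054}
          ]
        }
      ]
    },
    {
      "name": "amendment", "weight": 0.140,
      "children": [
        {"name": "cost", "comprehensive": 0.042},
        {"name": "amendment_hm", "comprehensive": 0.045},
        {"name": "stability", "comprehensive": 0.053}
      ]
    }
  ]
}
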