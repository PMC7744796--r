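{
  "states": [
    {
      "name": "apo_trans",
      "conducting": false
    },
    {
      "name": "apo_cis",
      "conducting": false
    },
    {
      "name": "bound_trans",
      "conducting": false
    },
    {
      "name": "bound_cis",
      "conducting": false
    },
    {
      "name": "open_trans",
      "conducting": true
    },
    {
      "name": "open_cis",
      "conducting": true
    }
  ],
  "transitions": [
    {
      "from": "apo_trans",
      "to": "apo_cis",
      "rate": 0.03,
      "ligand_dependent": false,
      "kind": "isomerization"
    },
    {
      "from": "apo_cis",
      "to": "apo_trans",
      "rate": 0.02,
      "ligand_dependent": false,
      "kind": "isomerization"
    },
    {
      "from": "apo_trans",
      "to": "bound_trans",
      "rate": 10,
      "ligand_dependent": true,
      "kind": "binding"
    },
    {
      "from": "bound_trans",
      "to": "apo_trans",
      "rate": 240,
      "ligand_dependent": false,
      "kind": "binding"
    },
    {
      "from": "apo_cis",
      "to": "bound_cis",
      "rate": 10,
      "ligand_dependent": true,
      "kind": "binding"
    },
    {
      "from": "bound_cis",
      "to": "apo_cis",
      "rate": 8000,
      "ligand_dependent": false,
      "kind": "binding"
    },
    {
      "from": "bound_trans",
      "to": "open_trans",
      "rate": 100,
      "ligand_dependent": false,
      "kind": "gating"
    },
    {
      "from": "open_trans",
      "to": "bound_trans",
      "rate": 900,
      "ligand_dependent": false,
      "kind": "gating"
    },
    {
      "from": "bound_cis",
      "to": "open_cis",
      "rate": 0.266953713670614,
      "ligand_dependent": false,
      "kind": "gating"
    },
    {
      "from": "open_cis",
      "to": "bound_cis",
      "rate": 0.973046286329386,
      "ligand_dependent": false,
      "kind": "gating"
    },
    {
      "from": "open_trans",
      "to": "open_cis",
      "rate": 0.0001,
      "ligand_dependent": false,
      "kind": "isomerization"
    },
    {
      "from": "open_cis",
      "to": "open_trans",
      "rate": 0.0009,
      "ligand_dependent": false,
      "kind": "isomerization"
    }
  ],
  "metadata": {
    "mechanism": "modulatory",
    "bound_isomerization": false
  }
}
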