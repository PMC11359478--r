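# Small, fully synthetic demonstration workshop: four climate hazards (as
# in the weighting walk-through), four transmission processes, four health
# outcomes, three scoring questions and five diseases.
criteria:
  hazard:
    - {id: warming, label: "Warming"}
    - {id: flooding, label: "Flooding, storms, and cyclones"}
    - {id: drought, label: "Drought"}
    - {id: sea_level_rise, label: "Sea level rise"}
  transmission:
    - {id: geographic_exposure, label: "Geographic exposure to infected hosts and vectors"}
    - {id: population_demographics, label: "Change in host or vector population demographics"}
    - {id: pathogen_evolution, label: "Evolutionary pressure on pathogens"}
    - {id: host_susceptibility, label: "Host susceptibility to infections"}
  outcome:
    - {id: severity, label: "Severity of disease"}
    - {id: prevention_control, label: "Ability to prevent and control"}
    - {id: transmissibility, label: "Transmissibility"}
    - {id: socioeconomic, label: "Socio-economic impacts"}
questions:
  - id: q_warming_evolution_mortality
    text: "Does warming impact the evolution of pathogens and lead to an increase in mortality?"
    hazard: warming
    transmission: pathogen_evolution
    outcome: severity
    options:
      - {text: "No change in case fatality rate", value: 0}
      - {text: "Increase case fatality rate by <5%", value: 1}
      - {text: "Increase case fatality rate by 5-10%", value: 2}
      - {text: "Increase case fatality rate by >10%", value: 3}
  - id: q_flooding_exposure_transmission
    text: "Does flooding increase geographic exposure to infected hosts and lead to increased transmission?"
    hazard: flooding
    transmission: geographic_exposure
    outcome: transmissibility
    options:
      - {text: "No change in transmission", value: 0}
      - {text: "Increase transmission in animals only", value: 1}
      - {text: "Increase transmission in humans only", value: 2}
      - {text: "Increase transmission in both animals and humans", value: 3}
  - id: q_drought_demographics_control
    text: "Do droughts change host population demographics in ways that hinder prevention and control?"
    hazard: drought
    transmission: population_demographics
    outcome: prevention_control
    options:
      - {text: "No change", value: 0}
      - {text: "Somewhat harder to control", value: 1}
      - {text: "Much harder to control", value: 2}
  - id: q_sealevel_susceptibility_socioeconomic
    text: "Does sea level rise alter host susceptibility with socio-economic consequences?"
    hazard: sea_level_rise
    transmission: host_susceptibility
    outcome: socioeconomic
    options:
      - {text: "No change", value: 0}
      - {text: "Local impact", value: 1}
      - {text: "Regional impact", value: 2}
      - {text: "National impact", value: 3}
diseases:
  - {id: leptospirosis, label: "Leptospirosis"}
  - {id: rvf, label: "Rift Valley fever"}
  - {id: wnv, label: "West Nile virus disease"}
  - {id: hendra, label: "Hendra virus disease"}
  - {id: rabies, label: "Rabies"}
participants: [expert_01, expert_02]
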