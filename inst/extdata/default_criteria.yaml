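# Default criterion vocabulary for climate-sensitive zoonosis prioritization.
# Workshops typically refine these sets to the hazards, transmission
# processes and health outcomes relevant to their jurisdiction.
criteria:
  hazard:
    - {id: warming, label: "Long-term temperature change (warming)"}
    - {id: precipitation_change, label: "Long-term precipitation change"}
    - {id: drought, label: "Droughts"}
    - {id: flooding, label: "Floods, storms, and cyclones"}
    - {id: heat_wave, label: "Heat waves"}
    - {id: sea_level_rise, label: "Sea level rise"}
    - {id: fire, label: "Fires"}
    - {id: wind_speed, label: "Wind speed"}
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
questions: []
diseases: []
participants: []
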