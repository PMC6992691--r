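# SIS Connect bundle schema, versioned. Column sets per table are drawn from
# the IUCN minimum required supporting information for Least Concern
# assessments; reconcile against current SIS Connect documentation before
# uploading to the live service. Changing this file changes the emitted
# schema without a code change.
version: "1.0"
key: internal_taxon_id
tables:
  taxonomy:
    columns: [internal_taxon_id, family, genus, species, taxonomicAuthority]
  assessments:
    columns: [internal_taxon_id, RedListCategory, RedListRationale,
              PopulationTrend, EcologicalSystem, Bibliography]
  allfields:
    columns: [internal_taxon_id, EOO_km2, AOO_km2, RecordCount, TDWGCount]
  countries:
    columns: [internal_taxon_id, country, iso2, l3_code, origin, presence]
    one_to_many: true
  credits:
    columns: [internal_taxon_id, credit_type, name]
    one_to_many: true
  habitats:
    columns: [internal_taxon_id, GeneralHabitats, GeneralHabitatsName]
    one_to_many: true
  plantspecific:
    columns: [internal_taxon_id, GrowthForms]
points:
  columns: [internal_taxon_id, binomial, longitude, latitude, presence,
            origin, seasonal]
defaults:
  RedListCategory: LC
  PopulationTrend: Unknown
  EcologicalSystem: Terrestrial
  presence: Extant
  origin: Native
  seasonal: Resident
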