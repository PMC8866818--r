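# Minimal hand-built core-vocabulary module: the OBO terms used by the
# subject/assay/feature instance pattern, with labels and a shallow subclass
# skeleton. This is a synthetic stand-in module so the pipeline runs without
# downloading the full source ontologies; full OBI/IAO/NPT modules can be
# loaded in its place with read_turtle().
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix obo: <http://purl.obolibrary.org/obo/> .

obo:BFO_0000001 a owl:Class ; rdfs:label "entity" .
obo:BFO_0000002 a owl:Class ; rdfs:subClassOf obo:BFO_0000001 ; rdfs:label "continuant" .
obo:BFO_0000003 a owl:Class ; rdfs:subClassOf obo:BFO_0000001 ; rdfs:label "occurrent" .
obo:BFO_0000004 a owl:Class ; rdfs:subClassOf obo:BFO_0000002 ; rdfs:label "independent continuant" .
obo:BFO_0000015 a owl:Class ; rdfs:subClassOf obo:BFO_0000003 ; rdfs:label "process" .
obo:BFO_0000023 a owl:Class ; rdfs:subClassOf obo:BFO_0000002 ; rdfs:label "role" .

obo:NCBITaxon_9606 a owl:Class ; rdfs:subClassOf obo:BFO_0000004 ; rdfs:label "Homo sapiens" .

obo:IAO_0000030 a owl:Class ; rdfs:subClassOf obo:BFO_0000002 ; rdfs:label "information content entity" .
obo:IAO_0000109 a owl:Class ; rdfs:subClassOf obo:IAO_0000030 ; rdfs:label "measurement datum" .
obo:IAO_0000101 a owl:Class ; rdfs:subClassOf obo:IAO_0000030 ; rdfs:label "image" .

obo:OBI_0000011 a owl:Class ; rdfs:subClassOf obo:BFO_0000015 ; rdfs:label "planned process" .
obo:OBI_0000070 a owl:Class ; rdfs:subClassOf obo:OBI_0000011 ; rdfs:label "assay" .
obo:NPT_0020000 a owl:Class ; rdfs:subClassOf obo:OBI_0000070 ; rdfs:label "Montreal cognitive assessment assay" .
obo:OBI_0001933 a owl:Class ; rdfs:subClassOf obo:IAO_0000030 ; rdfs:label "value specification" .
obo:OBI_0000097 a owl:Class ; rdfs:subClassOf obo:BFO_0000023 ; rdfs:label "study subject role" .

obo:IAO_0000219 a owl:ObjectProperty ; rdfs:label "denotes" .
obo:IAO_0000136 a owl:ObjectProperty ; rdfs:label "is about" .
obo:BFO_0000057 a owl:ObjectProperty ; rdfs:label "has participant" .
obo:BFO_0000051 a owl:ObjectProperty ; rdfs:label "has part" .
obo:RO_0000052 a owl:ObjectProperty ; rdfs:label "inheres in" .
obo:OBI_0000299 a owl:ObjectProperty ; rdfs:label "has specified output" .
obo:OBI_0000293 a owl:ObjectProperty ; rdfs:label "has specified input" .
obo:OBI_0000417 a owl:ObjectProperty ; rdfs:label "achieves planned objective" .
obo:OBI_0001938 a owl:ObjectProperty ; rdfs:label "has value specification" .
obo:OBI_0002135 a owl:DatatypeProperty ; rdfs:label "has specified value" .
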