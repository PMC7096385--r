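<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="model">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_ocdcea_c" name="Oleate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
          <rdf:Description rdf:about="#M_ocdcea_c"><bqbiol:is><rdf:Bag>
            <rdf:li rdf:resource="http://identifiers.org/chebi/CHEBI:30823"/>
          </rdf:Bag></bqbiol:is></rdf:Description>
        </rdf:RDF></annotation>
      </species>
      <species id="M_Rtotal_c" name="Rtotal" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
          <rdf:Description rdf:about="#M_Rtotal_c"><bqbiol:is><rdf:Bag>
            <rdf:li rdf:resource="http://identifiers.org/chebi/CHEBI:28868"/>
          </rdf:Bag></bqbiol:is></rdf:Description>
        </rdf:RDF></annotation>
      </species>
      <species id="M_hdca_c" name="Hexadecanoate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
          <rdf:Description rdf:about="#M_hdca_c"><bqbiol:is><rdf:Bag>
            <rdf:li rdf:resource="http://identifiers.org/chebi/CHEBI:7896"/>
          </rdf:Bag></bqbiol:is></rdf:Description>
        </rdf:RDF></annotation>
      </species>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_desat" name="R_desat" reversible="true" fast="false">
        <listOfReactants>
          <speciesReference species="M_hdca_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_ocdcea_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_pool" name="R_pool" reversible="true" fast="false">
        <listOfReactants>
          <speciesReference species="M_ocdcea_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_Rtotal_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
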