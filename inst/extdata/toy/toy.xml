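<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="toy">
<listOfCompartments>
<compartment id="c" name="cytosol" constant="true"/>
<compartment id="e" name="extracellular" constant="true"/>
</listOfCompartments>
<listOfSpecies>
<species id="M_glc_e" name="glucose" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>ORIGINAL_ID: glc[e]</p><p>FORMULA: C6H12O6</p></body></notes></species>
<species id="M_glc_c" name="glucose" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>ORIGINAL_ID: glc[c]</p><p>FORMULA: C6H12O6</p></body></notes></species>
<species id="M_lac_c" name="lactate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>ORIGINAL_ID: lac[c]</p><p>FORMULA: C3H6O3</p></body></notes></species>
</listOfSpecies>
<listOfReactions>
<reaction id="R_GLCt" reversible="false" fast="false"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>ORIGINAL_ID: GLCt</p><p>GENE_ASSOCIATION: glut1</p></body></notes><listOfReactants><speciesReference species="M_glc_e" stoichiometry="1" constant="true"/></listOfReactants><listOfProducts><speciesReference species="M_glc_c" stoichiometry="1" constant="true"/></listOfProducts></reaction>
<reaction id="R_GLYC" reversible="false" fast="false"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>ORIGINAL_ID: GLYC</p><p>GENE_ASSOCIATION: pfk or pk</p></body></notes><listOfReactants><speciesReference species="M_glc_c" stoichiometry="1" constant="true"/></listOfReactants><listOfProducts><speciesReference species="M_lac_c" stoichiometry="2" constant="true"/></listOfProducts></reaction>
<reaction id="R_EX_glc" reversible="true" fast="false"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>ORIGINAL_ID: EX_glc</p><p>EXCHANGE: true</p></body></notes><listOfReactants><speciesReference species="M_glc_e" stoichiometry="1" constant="true"/></listOfReactants></reaction>
</listOfReactions>
</model>
</sbml>
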