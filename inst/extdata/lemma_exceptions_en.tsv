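form	lemma
advised	advise
ate	eat
been	be
began	begin
better	good
caused	cause
changed	change
children	child
diagnosed	diagnose
diagnosing	diagnose
diagnosis	diagnosis
did	do
does	do
done	do
drank	drink
exercised	exercise
exercising	exercise
feet	foot
felt	feel
found	find
gave	give
given	give
goes	go
gone	go
got	get
had	have
has	have
having	have
improved	improve
increased	increase
is	be
knew	know
known	know
left	leave
lost	lose
made	make
managed	manage
men	man
people	person
quitting	quit
recovered	recover
reduced	reduce
said	say
saw	see
seen	see
shared	share
smoked	smoke
smoking	smoke
struggled	struggle
struggling	struggle
survived	survive
surviving	survive
taken	take
taught	teach
teeth	tooth
told	tell
took	take
treated	treat
was	be
went	go
were	be
women	woman
worse	bad
wrote	write
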