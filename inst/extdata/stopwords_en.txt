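# English stopwords, one token per line (matched after lowercasing).
a
about
after
again
all
am
an
and
any
are
as
at
be
because
been
before
being
but
by
can
could
did
do
does
doing
for
from
had
has
have
having
he
her
here
hers
him
his
i
if
in
into
is
it
its
just
me
more
most
my
no
nor
not
now
of
on
once
only
or
other
our
ours
out
over
own
she
so
some
such
than
that
the
their
theirs
them
then
there
these
they
this
those
through
to
too
under
until
up
very
was
we
were
what
when
where
which
while
who
whom
why
will
with
you
your
yours
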